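#' Empirical logit transform for incidence proportions
#'
#' `log((p + 0.5/n) / (1 - p + 0.5/n))`: the log-odds with a `0.5/n`
#' continuity correction so that proportions of exactly 0 or 1 map to finite
#' values.  Used for incidence traits (e.g. fraction of affected fruit per
#' plot) before mixed-model aggregation.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param n Count(s) the proportion is based on, `>= 1`; recycled.
#' @return Numeric vector of transformed values.
#' @examples
#' empirical_logit(0.5, 10)   # 0 by symmetry
#' empirical_logit(0, 10)     # log(0.05 / 1.05)
#' @export
empirical_logit <- function(p, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  log((p + 0.5 / n) / (1 - p + 0.5 / n))
}

#' Aggregate multi-season records into per-cultivar values
#'
#' REML fit of `value ~ cultivar + (1 | season) + (1 | season:year)` with the
#' cultivar effect fixed, via [lme4::lmer()].  Cultivar values are reported
#' under a sum-to-zero convention (centered), since only differences between
#' cultivars matter downstream; differences are invariant to the contrast
#' choice.  Random terms whose grouping factor has a single level are
#' dropped (their variance is reported as 0), so a one-season one-year data
#' set collapses to per-cultivar means.
#'
#' Incidence traits can be transformed with [empirical_logit()] before
#' fitting; the per-record count defaults to an `n_fruit` column when
#' present, falling back to `pseudo_n`.
#'
#' @param records Long-format data frame (`sample_id, season, year, trait,
#'   value`, optionally `n_fruit`).
#' @param trait Trait label to aggregate.
#' @param incidence Logical; empirical-logit transform values first.
#' @param pseudo_n Fallback count for the transform when `n_fruit` is absent.
#' @return A `cultivar_values` object: `values` (named, centered),
#'   `varcomp` (`season`, `season_year`, `residual`), `trait`, `n_records`.
#' @export
fit_cultivar_values <- function(records, trait, incidence = FALSE,
                                pseudo_n = 20) {
  stopifnot(is.data.frame(records))
  rec <- records[records$trait == trait, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for trait '", trait, "'")
  if (length(unique(rec$sample_id)) < 2)
    stop("need records for at least 2 cultivars")
  if (incidence) {
    nn <- if ("n_fruit" %in% names(rec)) rec$n_fruit else pseudo_n
    rec$value <- empirical_logit(rec$value, nn)
  }
  rec$sample_id <- factor(rec$sample_id)
  rec$season <- factor(rec$season)
  rec$sy <- interaction(rec$season, rec$year, drop = TRUE)

  use_season <- nlevels(rec$season) >= 2
  use_sy <- nlevels(rec$sy) > nlevels(rec$season)
  vc <- c(season = 0, season_year = 0, residual = 0)

  if (!use_season && !use_sy) {
    fit <- stats::lm(value ~ 0 + sample_id, data = rec)
    est <- stats::coef(fit)
    vc["residual"] <- summary(fit)$sigma^2
    if (is.na(vc["residual"])) vc["residual"] <- 0
  } else {
    terms <- c(if (use_season) "(1 | season)", if (use_sy) "(1 | sy)")
    form <- stats::as.formula(paste("value ~ 0 + sample_id +",
                                    paste(terms, collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = rec, REML = TRUE)))
    est <- lme4::fixef(fit)
    vcs <- as.data.frame(lme4::VarCorr(fit))
    get_vc <- function(grp) {
      v <- vcs$vcov[vcs$grp == grp]
      if (length(v)) v else 0
    }
    vc["season"] <- get_vc("season")
    vc["season_year"] <- get_vc("sy")
    vc["residual"] <- get_vc("Residual")
  }
  names(est) <- sub("^sample_id", "", names(est))
  dropped <- setdiff(levels(rec$sample_id), names(est))
  if (length(dropped))
    warning("non-estimable cultivar(s) excluded: ",
            paste(dropped, collapse = ", "))
  est <- est - mean(est)          # sum-to-zero convention
  structure(list(trait = trait, values = est, varcomp = vc,
                 n_records = nrow(rec)),
            class = "cultivar_values")
}

#' @export
print.cultivar_values <- function(x, ...) {
  cat("cultivar_values ('", x$trait, "'): ", length(x$values),
      " cultivars from ", x$n_records, " records\n  variance components: ",
      paste(sprintf("%s=%.3g", names(x$varcomp), x$varcomp),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Coerce phenotype holders to a named numeric vector
#' @noRd
.as_pheno_vector <- function(y) {
  if (inherits(y, "cultivar_values")) return(y$values)
  if (is.numeric(y) && !is.null(names(y))) return(y)
  stop("y must be a cultivar_values object or a named numeric vector")
}
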