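#' Mixed-effects model of component weights
#'
#' Fits a mixed model of one component weight on cortical area, lesion
#' volume, trial type and all their interactions (fixed effects), with a
#' random intercept per animal. Factors use effects coding (each factor's
#' level codes sum to zero) so level effects are deviations from the grand
#' mean; lesion volume is standardized internally and reported per standard
#' deviation. The default family is Gaussian with identity link; the
#' `quasibinomial` variant reproduces a binomial/logit specification on
#' continuous weights via penalized quasi-likelihood (the weights are
#' affinely rescaled into (0, 1) before the logit fit).
#'
#' @param table weight table: data.frame with `animal`, `area`,
#'   `trial_type`, `lesion_volume` and the response column.
#' @param response name of the weight column to model (e.g. `"w2"` or
#'   `"w3"`).
#' @param family `"gaussian"` (identity link, REML, Satterthwaite degrees of
#'   freedom) or `"quasibinomial"` (logit link, penalized quasi-likelihood).
#' @return object of class `coef_report`: data.frame with `term`,
#'   `estimate`, `se`, `df`, `p`; attributes `response`, `family`, `n_obs`,
#'   `fit` (the underlying model object), `levels` (factor level maps).
#' @export
fit_weight_model <- function(table, response = "w2",
                             family = c("gaussian", "quasibinomial")) {
  family <- match.arg(family)
  if (!response %in% names(table)) stop("no column '", response, "' in table")
  need <- c("animal", "area", "trial_type", "lesion_volume")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  if (anyNA(table[, c(need, response)])) stop("missing values in covariates or response")
  d <- data.frame(
    y = table[[response]],
    animal = factor(table$animal),
    area = factor(table$area, levels = intersect(c("RFA", "S1"),
                                                 unique(table$area))),
    trial_type = factor(table$trial_type,
                        levels = intersect(c("Solenoid", "ICMS", "ICMS+Solenoid"),
                                           unique(table$trial_type))),
    lesion_z = as.numeric(scale(table$lesion_volume)))
  if (nlevels(d$area) < 2 || nlevels(d$trial_type) < 2)
    stop("each factor needs at least 2 levels")
  if (nlevels(d$animal) < 2)
    stop("random intercept needs at least 2 animals")
  if (stats::sd(table$lesion_volume) == 0)
    stop("singular design: lesion_volume is constant (aliased with intercept)")
  contrasts(d$area) <- stats::contr.sum(nlevels(d$area))
  contrasts(d$trial_type) <- stats::contr.sum(nlevels(d$trial_type))
  fixed <- y ~ area * lesion_z * trial_type
  mm <- stats::model.matrix(fixed, d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("singular design: aliased term(s) ", paste(aliased, collapse = ", "))
  }
  if (family == "gaussian") {
    fit <- lmerTest::lmer(y ~ area * lesion_z * trial_type + (1 | animal),
                          data = d)
    cf <- stats::coef(summary(fit))
    rep <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"], df = cf[, "df"],
                      p = cf[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  } else {
    eps <- 0.025
    rng <- range(d$y)
    d$y01 <- (d$y - rng[1]) / diff(rng) * (1 - 2 * eps) + eps
    fit <- MASS::glmmPQL(y01 ~ area * lesion_z * trial_type,
                         random = ~ 1 | animal,
                         family = stats::quasibinomial(link = "logit"),
                         data = d, verbose = FALSE)
    tt <- summary(fit)$tTable
    rep <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      se = tt[, "Std.Error"], df = tt[, "DF"],
                      p = tt[, "p-value"], stringsAsFactors = FALSE)
  }
  ## readable effects-coded term names: area1 -> area[RFA], etc.
  pretty <- function(nm) {
    nm <- gsub("area1", paste0("area[", levels(d$area)[1], "]"), nm, fixed = TRUE)
    for (i in seq_len(nlevels(d$trial_type) - 1))
      nm <- gsub(paste0("trial_type", i),
                 paste0("trial_type[", levels(d$trial_type)[i], "]"),
                 nm, fixed = TRUE)
    nm
  }
  rep$term <- pretty(rep$term)
  rownames(rep) <- NULL
  structure(rep, class = c("coef_report", "data.frame"),
            response = response, family = family, n_obs = nrow(d),
            fit = fit,
            levels = list(area = levels(d$area),
                          trial_type = levels(d$trial_type)))
}

#' @export
print.coef_report <- function(x, ...) {
  cat(sprintf("Mixed-model coefficient report: response %s, family %s, n = %d\n",
              attr(x, "response"), attr(x, "family"), attr(x, "n_obs")))
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, 5)
  df$se <- signif(df$se, 5)
  df$df <- round(df$df, 1)
  df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract the effects-coded level estimate for a factor level
#'
#' With a two-level effects-coded factor the second level's effect is the
#' negative of the first; this returns the (estimate, se, df, p) row for the
#' requested level, negating the estimate when the level is the implicit one.
#'
#' @param report a `coef_report`.
#' @param factor_name `"area"` or `"trial_type"`.
#' @param level the level of interest.
#' @return one-row data.frame (`term`, `estimate`, `se`, `df`, `p`).
#' @export
level_effect <- function(report, factor_name, level) {
  levs <- attr(report, "levels")[[factor_name]]
  if (!level %in% levs) stop("unknown level ", level)
  if (length(levs) != 2) stop("level_effect implemented for 2-level factors")
  shown <- paste0(factor_name, "[", levs[1], "]")
  row <- report[report$term == shown, , drop = FALSE]
  if (level != levs[1]) {
    row$estimate <- -row$estimate
    row$term <- paste0(factor_name, "[", level, "]")
  }
  as.data.frame(row)
}

#' Cell means and standard errors of component weights
#'
#' @param table weight table with `area`, `trial_type` and weight columns
#'   (`w1`, `w2`, ...).
#' @param weights names of the weight columns to summarize.
#' @return data.frame, one row per area x trial type with `n`, and
#'   `<w>_mean` / `<w>_sem` per weight; cells with fewer than 2 rows are
#'   omitted (attribute `omitted` lists them).
#' @export
summarize_weights <- function(table, weights = intersect(c("w1", "w2", "w3"),
                                                         names(table))) {
  cells <- unique(table[, c("area", "trial_type")])
  rows <- list(); omitted <- character(0)
  for (i in seq_len(nrow(cells))) {
    sel <- table$area == cells$area[i] & table$trial_type == cells$trial_type[i]
    n <- sum(sel)
    if (n < 2) {
      omitted <- c(omitted, paste(cells$area[i], cells$trial_type[i], sep = ":"))
      next
    }
    r <- data.frame(area = cells$area[i], trial_type = cells$trial_type[i],
                    n = n, stringsAsFactors = FALSE)
    for (w in weights) {
      v <- table[[w]][sel]
      r[[paste0(w, "_mean")]] <- mean(v)
      r[[paste0(w, "_sem")]] <- stats::sd(v) / sqrt(n)
    }
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Cavalieri estimator of lesion volume
#'
#' Unbiased stereological volume estimate from the marked lesion areas of
#' serial sections: section sampling interval times the summed areas.
#'
#' @param areas_mm2 marked lesion area per analyzed section, mm2.
#' @param interval_mm section sampling interval, mm (default 0.6).
#' @return volume, mm3.
#' @export
cavalieri_volume <- function(areas_mm2, interval_mm = 0.6) {
  if (length(areas_mm2) < 1) stop("at least one section required")
  if (any(areas_mm2 < 0)) stop("section areas must be >= 0")
  if (interval_mm <= 0) stop("sampling interval must be > 0")
  interval_mm * sum(areas_mm2)
}
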