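# Random-intercept linear mixed model linking per-nucleus pseudotime to
# donor-level pathology, genotype and age:
#   t ~ amyloid + tau + TREM2 + APOE + age + (1 | sample)
# with E3/E3 and WT as the genotype reference levels. Estimation delegates
# to lme4 (REML); this module owns the design coding and the output schema.

#' Fit the pathology random-intercept mixed model
#'
#' Fixed effects: binary amyloid and tau pathology, TREM2 R47H (vs WT),
#' APOE E3/E4 and E4/E4 (vs E3/E3), age at death. Random effect: one
#' intercept per donor. Wald p-values (`2 * pnorm(-|t|)`) are reported for
#' the fixed effects. Genotype levels not present in the cohort are dropped
#' (no coefficient is emitted for them); genuinely collinear covariates
#' raise an error naming the offending column.
#'
#' @param t numeric pseudotime per nucleus.
#' @param meta data.frame with columns `sample`, `amyloid`, `tau`, `apoe`,
#'   `trem2`, `age`, rows aligned with `t`.
#' @return `lmm_fit`: list with `coefficients` (data.frame term, estimate,
#'   se, statistic, p.value), `ranef_var`, `resid_var`, `n`, `n_groups`.
#' @export
fit_random_intercept_lmm <- function(t, meta) {
  req <- c("sample", "amyloid", "tau", "apoe", "trem2", "age")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(t = as.numeric(t),
                   sample = as.character(meta$sample),
                   amyloid = as.numeric(meta$amyloid),
                   tau = as.numeric(meta$tau),
                   apoe = factor(meta$apoe, levels = c("E3/E3", "E3/E4", "E4/E4")),
                   trem2 = factor(meta$trem2, levels = c("WT", "R47H")),
                   age = as.numeric(meta$age))
  # genotype levels absent from a cohort contribute no coefficient
  df$apoe <- droplevels(df$apoe)
  df$trem2 <- droplevels(df$trem2)
  if (any(!complete.cases(df))) stop("covariates contain missing values", call. = FALSE)
  if (length(unique(df$sample)) < 2) stop("need at least two donors", call. = FALSE)
  if (!all(df$amyloid %in% c(0, 1)) || !all(df$tau %in% c(0, 1))) {
    stop("amyloid and tau must be coded 0/1", call. = FALSE)
  }

  # degenerate response: nothing to estimate
  if (var(df$t) == 0) {
    terms <- c("(Intercept)", "amyloid", "tau", "trem2R47H",
               "apoeE3/E4", "apoeE4/E4", "age")
    coefs <- data.frame(term = terms,
                        estimate = c(df$t[1], rep(0, length(terms) - 1)),
                        se = 0, statistic = NA_real_, p.value = NA_real_,
                        stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs, ranef_var = 0, resid_var = 0,
                          n = nrow(df), n_groups = length(unique(df$sample))),
                     class = "lmm_fit"))
  }

  # single-level factors (e.g. an all-WT cohort) carry no contrast
  fixed_terms <- c("amyloid", "tau",
                   if (nlevels(df$trem2) > 1) "trem2",
                   if (nlevels(df$apoe) > 1) "apoe",
                   "age")
  fixed_fml <- paste(fixed_terms, collapse = " + ")
  mm <- model.matrix(stats::as.formula(paste("~", fixed_fml)), df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(stats::as.formula(paste("t ~", fixed_fml, "+ (1 | sample)")),
               data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], statistic = sm[, "t value"],
                      p.value = 2 * pnorm(-abs(sm[, "t value"])),
                      stringsAsFactors = FALSE, row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 ranef_var = vc$vcov[vc$grp == "sample"],
                 resid_var = vc$vcov[vc$grp == "Residual"],
                 n = nrow(df),
                 n_groups = length(unique(df$sample))),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM: %d nuclei, %d donors\n", x$n, x$n_groups))
  cat(sprintf("donor intercept variance %.4g, residual variance %.4g\n",
              x$ranef_var, x$resid_var))
  print(x$coefficients, digits = 4)
  invisible(x)
}
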