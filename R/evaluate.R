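# Profile-comparison statistics (f2 similarity factor, profile RMSEP),
# DR-content normalisation, the 3^3 factorial standardized-effects
# analysis, and the ANN-vs-PLS comparison table.

#' f2 dissolution-profile similarity factor
#'
#' `f2 = 50 * log10(100 * (1 + mean(w * (R - T)^2))^(-0.5))`. Identical
#' profiles give 100; 50-100 is the conventional equivalence range. All
#' points enter by default; the regulatory convention of truncating the
#' comparison one point after the reference exceeds 85 % released is
#' available via `truncate_85` but is off by default, full profiles being
#' compared here.
#'
#' @param R,T Reference (measured) and test (predicted) profiles, equal
#'   length.
#' @param w Optional per-point weights (default all 1).
#' @param truncate_85 Truncate after the reference first exceeds 85 %?
#' @return The f2 value (unitless).
#' @export
f2_similarity <- function(R, T, w = NULL, truncate_85 = FALSE) {
  if (length(R) != length(T)) stop("profile length mismatch")
  if (length(R) < 1) stop("empty profiles")
  if (is.null(w)) w <- rep(1, length(R)) else if (length(w) != length(R))
    stop("weight length mismatch")
  if (truncate_85 && any(R >= 85)) {
    keep <- seq_len(min(which(R >= 85)))
    R <- R[keep]; T <- T[keep]; w <- w[keep]
  }
  50 * log10(100 / sqrt(1 + mean(w * (R - T)^2)))
}

#' Root mean square prediction error between two profiles
#'
#' @param R,T Profiles of equal length.
#' @return `sqrt(mean((R - T)^2))`, in % released.
#' @export
profile_rmsep <- function(R, T) {
  if (length(R) != length(T)) stop("profile length mismatch")
  sqrt(mean((R - T)^2))
}

#' Normalise a profile to the reference drug content
#'
#' Rescales released values from a tablet of true drug content `dr_true` to
#' the reference content (the study's 8 % centre point), i.e. multiplies by
#' `dr_ref / dr_true`.
#'
#' @param profile Numeric profile (% released).
#' @param dr_true True drug content, % w/w (> 0).
#' @param dr_ref Reference content, % w/w.
#' @return Rescaled profile.
#' @export
normalize_to_mean_dr <- function(profile, dr_true, dr_ref = 8) {
  if (dr_true <= 0) stop("dr_true must be positive")
  profile * dr_ref / dr_true
}

#' Standardized-effects analysis of the factorial block
#'
#' Fits, by least squares, the 10-term response-surface model (intercept,
#' the three linear factor effects, their quadratics, and the three
#' linear-by-linear interactions) to the dissolution value at one time
#' point, on the 27 factorial settings' tablets. Factors are coded
#' -1/0/+1 from their nominal levels; responses are first normalised to
#' the 8 % reference drug content. The standardized effect of a term is its
#' t statistic; significance is judged at `p = 0.05` on the residual
#' degrees of freedom. Rows are ordered by decreasing |t| (Pareto order).
#'
#' @param tablets Tablet table from [generate_dataset()] (or equivalent),
#'   containing the full factorial block.
#' @param profiles Matrix of measured profiles, rows matching `tablets`.
#' @param times Time grid of the profile columns.
#' @param response_time Time point (minutes) whose dissolution value is the
#'   response; the study analyses 15 and 960 min.
#' @param alpha Significance level.
#' @return Data frame with `term`, `estimate`, `std_error`, `t_value`
#'   (standardized effect), `p_value`, `significant`.
#' @export
effects_analysis <- function(tablets, profiles, times = dissolution_time_grid(),
                             response_time = 15, alpha = 0.05) {
  fact <- tablets$origin == "factorial"
  tab <- tablets[fact, ]
  need <- expand.grid(dr = c(6, 8, 10), hpmc = c(10, 20, 30),
                      force = c(63.8, 95.7, 127.6))
  have <- unique(tab[, c("dr_nominal", "hpmc_nominal", "force")])
  if (nrow(merge(need, have,
                 by.x = c("dr", "hpmc", "force"),
                 by.y = c("dr_nominal", "hpmc_nominal", "force"))) < 27)
    stop("missing factorial cells: all 27 factorial settings are required")
  col <- match(response_time, times)
  if (is.na(col)) stop("response_time ", response_time, " not on the time grid")
  y <- profiles[fact, col] * 8 / tab$dr_true
  d <- data.frame(
    y = y,
    dr = (tab$dr_nominal - 8) / 2,
    hpmc = (tab$hpmc_nominal - 20) / 10,
    force = (tab$force - 95.7) / 31.9
  )
  fit <- stats::lm(y ~ dr + hpmc + force + I(dr^2) + I(hpmc^2) + I(force^2)
                   + dr:hpmc + dr:force + hpmc:force, data = d)
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    std_error = cf[, 2], t_value = cf[, 3],
                    p_value = cf[, 4],
                    significant = cf[, 4] < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$t_value)), ]
}

#' Per-tablet f2/RMSEP report for a set of predicted profiles
#'
#' @param predicted,reference Matrices of profiles (rows = tablets).
#' @param tablet_ids Row identifiers.
#' @param model Label for the predicting model.
#' @return An object of class `f2_report`: per-tablet data frame (`f2`,
#'   `rmsep`, `equivalent` = 50 <= f2 <= 100) plus `mean_f2`.
#' @export
f2_report <- function(predicted, reference, tablet_ids = rownames(reference),
                      model = "model") {
  predicted <- as.matrix(predicted); reference <- as.matrix(reference)
  stopifnot(all(dim(predicted) == dim(reference)))
  f2 <- vapply(seq_len(nrow(reference)), function(i)
    f2_similarity(reference[i, ], predicted[i, ]), numeric(1))
  rmsep <- vapply(seq_len(nrow(reference)), function(i)
    profile_rmsep(reference[i, ], predicted[i, ]), numeric(1))
  structure(list(
    model = model,
    per_tablet = data.frame(tablet_id = tablet_ids %||%
                              paste0("t", seq_along(f2)),
                            f2 = f2, rmsep = rmsep,
                            equivalent = f2 >= 50 & f2 <= 100,
                            stringsAsFactors = FALSE),
    mean_f2 = mean(f2)),
    class = "f2_report")
}

#' @export
print.f2_report <- function(x, ...) {
  cat("<f2_report>", x$model, "- mean f2:", round(x$mean_f2, 2),
      sprintf("(%d/%d equivalent)\n", sum(x$per_tablet$equivalent),
              nrow(x$per_tablet)))
  invisible(x)
}

#' Compare network and direct-PLS f2 reports
#'
#' @param ann_report,pls_report [f2_report()]s over the same tablets.
#' @return Data frame: per-model mean f2, their difference, and per-model
#'   equivalence counts.
#' @export
compare_models <- function(ann_report, pls_report) {
  if (!identical(ann_report$per_tablet$tablet_id,
                 pls_report$per_tablet$tablet_id))
    stop("tablet-set mismatch between reports")
  data.frame(
    model = c(ann_report$model, pls_report$model),
    mean_f2 = c(ann_report$mean_f2, pls_report$mean_f2),
    diff_vs_other = c(ann_report$mean_f2 - pls_report$mean_f2,
                      pls_report$mean_f2 - ann_report$mean_f2),
    n_equivalent = c(sum(ann_report$per_tablet$equivalent),
                     sum(pls_report$per_tablet$equivalent)),
    n_tablets = nrow(ann_report$per_tablet),
    stringsAsFactors = FALSE
  )
}
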