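# Scoring against ground truth and parameter-grid tuning.
#
# Attribution is scored as a confusion matrix over (sample x fecal category)
# calls; the tuning objective ranks parameter sets by negative predictive
# value (NPV), breaking ties by higher sensitivity, then higher specificity,
# then by the parameter values themselves so the order is total and
# deterministic. Apportionment is scored as the Pearson correlation between
# predicted and true portions; cell-fraction accuracy as an ordinary
# least-squares fit of truth on prediction (reported, never auto-applied).

#' Score attribution calls against ground truth
#'
#' @param calls data.frame with columns \code{sample_id}, \code{category},
#'   \code{present} — e.g. row-bound \code{$calls} of several
#'   \code{\link{sample_report}}s. Screen rows are ignored; only
#'   (sample, category) pairs in the truth table are scored.
#' @param truth data.frame (or TSV path) with columns \code{sample_id},
#'   \code{category}, \code{true_cell_fraction}; a category is truly present
#'   when its fraction is > 0. Every truth pair must have a call, and every
#'   called sample must appear in the truth (hard errors otherwise).
#' @return An object of class \code{attribution_score}: list with \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}, \code{sensitivity},
#'   \code{specificity}, \code{npv}, \code{ppv} (rates with a zero
#'   denominator are NA, not 0).
#' @export
score_attribution <- function(calls, truth) {
  truth <- as_tsv_table(truth, c("sample_id", "category", "true_cell_fraction"))
  extra <- setdiff(unique(calls$sample_id), unique(truth$sample_id))
  if (length(extra) > 0L) {
    stop("sample(s) in calls missing from truth: ", paste(extra, collapse = ", "))
  }
  key <- function(d) paste(d$sample_id, d$category, sep = "\r")
  m <- match(key(truth), key(calls))
  if (anyNA(m)) {
    miss <- truth[is.na(m), c("sample_id", "category")]
    stop("truth pair(s) without a call: ",
         paste(miss$sample_id, miss$category, sep = "/", collapse = ", "))
  }
  pred <- calls$present[m]
  real <- truth$true_cell_fraction > 0
  tp <- sum(pred & real); fp <- sum(pred & !real)
  fn <- sum(!pred & real); tn <- sum(!pred & !real)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 npv = rate(tn, tn + fn),
                 ppv = rate(tp, tp + fp)),
            class = "attribution_score")
}

#' @export
print.attribution_score <- function(x, ...) {
  cat(sprintf("attribution_score: TP %d FP %d FN %d TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  NPV %.3f  PPV %.3f\n",
              x$sensitivity, x$specificity, x$npv, x$ppv))
  invisible(x)
}

# true portions per sample from true fractions: fraction over the sum of
# positive fractions; all-zero samples give all-zero portions
true_portions <- function(truth) {
  out <- numeric(nrow(truth))
  for (s in unique(truth$sample_id)) {
    i <- truth$sample_id == s
    tot <- sum(truth$true_cell_fraction[i])
    if (tot > 0) out[i] <- truth$true_cell_fraction[i] / tot
  }
  out
}

#' Score apportionment against ground truth
#'
#' Pearson correlation between predicted and true source portions over all
#' (sample, fecal category) pairs of the truth table. Sources not called
#' present predict a portion of 0; true portions are the true fractions
#' renormalized over each sample's truly present sources.
#'
#' @param portions data.frame with columns \code{sample_id},
#'   \code{category}, \code{portion} for present sources (absent pairs are
#'   taken as 0).
#' @param truth ground-truth table as in \code{\link{score_attribution}}.
#' @return Pearson r, or NA when undefined (constant vector); requires at
#'   least 3 pairs.
#' @export
score_apportionment <- function(portions, truth) {
  truth <- as_tsv_table(truth, c("sample_id", "category", "true_cell_fraction"))
  if (nrow(truth) < 3L) stop("need at least 3 (sample, category) pairs")
  key <- paste(truth$sample_id, truth$category, sep = "\r")
  pred <- rep(0, nrow(truth))
  if (nrow(portions) > 0L) {
    m <- match(paste(portions$sample_id, portions$category, sep = "\r"), key)
    pred[m[!is.na(m)]] <- portions$portion[!is.na(m)]
  }
  tru <- true_portions(truth)
  if (stats::sd(pred) == 0 || stats::sd(tru) == 0) return(NA_real_)
  stats::cor(pred, tru)
}

#' Linear calibration of predicted cell fractions
#'
#' Ordinary least squares of true on predicted cell fractions. The fit is
#' diagnostic — a slope well above 1 indicates systematic underestimation —
#' and is never applied to the predictions automatically.
#'
#' @param predicted,truth numeric vectors of paired predicted and true cell
#'   fractions (at least 3 pairs; the predictor must not be constant).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
calibrate_cell_fractions <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0) stop("degenerate fit: constant predictor")
  fit <- stats::lm(truth ~ predicted)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Default bioinformatic parameter grid
#'
#' Identity \{85, 87, 89, 91, 93, 95, 97, 99\} x overlap \{30, 50, 70, 90\}
#' x masking \{0, 25, 50, 75\} x LOD \{0.1, 0.01, 0.001, 1e-4, 1e-5\}:
#' 640 combinations bracketing the tuned optimum (93, 70, 0, 0.01).
#'
#' @return An object of class \code{parameter_grid}: list of the four axis
#'   vectors with an \code{n_combinations} field.
#' @export
default_parameter_grid <- function() {
  parameter_grid(identities = c(85, 87, 89, 91, 93, 95, 97, 99),
                 overlaps = c(30, 50, 70, 90),
                 maskings = c(0, 25, 50, 75),
                 lods = c(0.1, 0.01, 0.001, 1e-4, 1e-5))
}

#' Construct a parameter grid
#'
#' @param identities minimum alignment identities, percent, in (0, 100].
#' @param overlaps minimum alignment-to-read overlaps, percent, in (0, 100].
#' @param maskings coverage masking percentages in [0, 100).
#' @param lods limits of detection, percent relative abundance.
#' @return a \code{parameter_grid}.
#' @export
parameter_grid <- function(identities, overlaps, maskings, lods) {
  stopifnot(length(identities) > 0, length(overlaps) > 0,
            length(maskings) > 0, length(lods) > 0,
            all(identities > 0 & identities <= 100),
            all(overlaps > 0 & overlaps <= 100),
            all(maskings >= 0 & maskings < 100),
            all(lods >= 0))
  structure(list(identities = identities, overlaps = overlaps,
                 maskings = maskings, lods = lods,
                 n_combinations = length(identities) * length(overlaps) *
                   length(maskings) * length(lods)),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter_grid: %d combinations\n", x$n_combinations))
  cat("  identities:", paste(x$identities, collapse = ", "), "\n")
  cat("  overlaps:  ", paste(x$overlaps, collapse = ", "), "\n")
  cat("  maskings:  ", paste(x$maskings, collapse = ", "), "\n")
  cat("  lods:      ", paste(x$lods, collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the parameter grid and rank by NPV
#'
#' Re-runs filtering, depth, cell fractions, attribution, and apportionment
#' for every parameter combination and scores each against the ground
#' truth. Alignments are parsed once per sample up front; filtering is done
#' once per (identity, overlap) pair and the depth profile once per
#' (identity, overlap, masking), then reused across LODs — equivalent to,
#' but much cheaper than, recomputing everything per combination.
#'
#' The GEQ of each sample is fixed across the grid (it is a property of the
#' whole metagenome, not of the mapping thresholds).
#'
#' @param samples list of samples, each a list with \code{sample_id},
#'   \code{alignments} (from \code{\link{parse_alignments}}) and \code{geq}
#'   (a \code{geq_estimate}).
#' @param db a \code{source_db}.
#' @param grid a \code{parameter_grid} (default
#'   \code{\link{default_parameter_grid}()}).
#' @param truth ground-truth table as in \code{\link{score_attribution}}.
#' @param min_reads,min_breadth detection rule passed to
#'   \code{\link{cell_fractions}}.
#' @return An object of class \code{tuning_result}: data.frame with one row
#'   per combination (parameters, confusion counts, sensitivity,
#'   specificity, npv, ppv, apportionment_r, calibration slope/intercept/r2,
#'   rank), ordered by rank.
#' @export
run_parameter_grid <- function(samples, db, grid = default_parameter_grid(),
                               truth, min_reads = 1, min_breadth = 0) {
  stopifnot(inherits(grid, "parameter_grid"))
  truth <- as_tsv_table(truth, c("sample_id", "category", "true_cell_fraction"))
  truth_key <- paste(truth$sample_id, truth$category, sep = "\r")

  rows <- vector("list", grid$n_combinations)
  r <- 0L
  for (ident in grid$identities) {
    for (ov in grid$overlaps) {
      filtered <- lapply(samples, function(s) {
        filter_alignments(s$alignments, min_identity = ident, min_overlap = ov)
      })
      for (m in grid$maskings) {
        fracs <- lapply(seq_along(samples), function(k) {
          d <- compute_depth(filtered[[k]], db, masking_percent = m,
                             sample_id = samples[[k]]$sample_id)
          cell_fractions(d, db, samples[[k]]$geq,
                         min_reads = min_reads, min_breadth = min_breadth)
        })
        pred_cf <- unlist(lapply(fracs, function(f) {
          m2 <- match(truth_key, paste(f$sample_id, f$category, sep = "\r"))
          f$cell_fraction[m2[!is.na(m2)]]
        }))
        # paired true fractions in the same order as pred_cf
        true_cf <- unlist(lapply(fracs, function(f) {
          keep <- !is.na(match(truth_key, paste(f$sample_id, f$category, sep = "\r")))
          truth$true_cell_fraction[keep]
        }))
        for (lod in grid$lods) {
          reports <- lapply(fracs, sample_report, lod_percent = lod)
          calls <- do.call(rbind, lapply(reports, function(x) as.data.frame(x$calls)))
          sc <- score_attribution(calls, truth)
          portions <- do.call(rbind, lapply(reports, function(x) {
            data.frame(sample_id = rep(x$sample_id, length(x$portions)),
                       category = names(x$portions),
                       portion = unname(x$portions), stringsAsFactors = FALSE)
          }))
          app_r <- tryCatch(score_apportionment(portions, truth),
                            error = function(e) NA_real_)
          calib <- tryCatch(calibrate_cell_fractions(pred_cf, true_cf),
                            error = function(e) list(slope = NA_real_,
                                                     intercept = NA_real_,
                                                     r_squared = NA_real_))
          r <- r + 1L
          rows[[r]] <- data.frame(
            min_identity = ident, min_overlap = ov, masking_percent = m,
            lod_percent = lod, tp = sc$tp, fp = sc$fp, fn = sc$fn, tn = sc$tn,
            sensitivity = sc$sensitivity, specificity = sc$specificity,
            npv = sc$npv, ppv = sc$ppv, apportionment_r = app_r,
            calibration_slope = calib$slope,
            calibration_intercept = calib$intercept,
            calibration_r2 = calib$r_squared)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(res$npv), -Inf, res$npv),
               -ifelse(is.na(res$sensitivity), -Inf, res$sensitivity),
               -ifelse(is.na(res$specificity), -Inf, res$specificity),
               res$min_identity, res$min_overlap, res$masking_percent,
               res$lod_percent)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res, class = c("tuning_result", "data.frame"))
}
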