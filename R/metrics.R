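check_screen_labels <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("ligand", "decoy")))
    stop('labels must be "ligand" or "decoy"')
  if (length(unique(labels)) < 2L)
    stop("enrichment metrics need at least one ligand and one decoy")
  labels
}

#' ROC curve of a ranked screen
#'
#' Ranks molecules ascending by score (lower = better docking energy) and
#' traces the fraction of ligands recovered (TPR) against the fraction of
#' decoys passed (FPR).  Tied scores advance as one block, which draws the
#' trapezoid through the tie (equivalent to averaging over all orderings of
#' the tie); all-tied input therefore gives the diagonal.  The curve always
#' starts at (0,0) and ends at (1,1).
#'
#' @param scores numeric scores, lower is better.
#' @param labels `"ligand"` / `"decoy"` per molecule.
#' @return A `roc_curve` data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_screen_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  ends <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l == "ligand")[ends]
  fp <- cumsum(l == "decoy")[ends]
  out <- data.frame(fpr = c(0, fp / sum(l == "decoy")),
                    tpr = c(0, tp / sum(l == "ligand")))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area; 0.5 is random, 1 is perfect separation of ligands from
#' decoys.
#'
#' @param curve a `roc_curve` from [roc_points()].
#' @return AUC as a fraction in [0, 1].
#' @export
roc_auc <- function(curve) {
  f <- curve$fpr
  t <- curve$tpr
  sum(diff(f) * (head(t, -1) + t[-1]) / 2)
}

#' Enrichment factor at a ranked-list fraction
#'
#' `EF_f` is the fraction of all ligands found in the top `ceiling(f * N)`
#' of the ranked list, divided by `f`; `EF_0.01` (EF1) is the familiar
#' 1%-point statistic.  Its maximum is `1/f`, and `EF_1` is 1 for any
#' screen.  Ranking is by ascending score with stable ties.
#'
#' @param scores numeric scores, lower is better.
#' @param labels `"ligand"` / `"decoy"`.
#' @param fraction top fraction of the list, default 0.01.
#' @return The enrichment factor (a ratio).
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.01) {
  labels <- check_screen_labels(labels)
  n <- length(scores)
  if (fraction * n < 1)
    stop(sprintf(
      "top fraction %.4g of %d compounds selects less than one molecule; use a larger set or fraction",
      fraction, n))
  k <- ceiling(fraction * n)
  top <- order(scores)[seq_len(k)]
  (sum(labels[top] == "ligand") / sum(labels == "ligand")) / fraction
}

log_auc_integral <- function(curve, lambda) {
  f <- curve$fpr
  t <- curve$tpr
  # tpr at the clip point, interpolated on the segment straddling lambda
  j <- max(which(f <= lambda))
  if (j == length(f)) return(0)  # degenerate; lambda >= 1 is rejected upstream
  tl <- t[j] + (t[j + 1L] - t[j]) * (lambda - f[j]) / (f[j + 1L] - f[j])
  keep <- f > lambda
  vf <- c(lambda, f[keep])
  vt <- c(tl, t[keep])
  # exact integral of the piecewise-linear curve against d(log10 f):
  # on a segment tpr = a + b f, the contribution is (a ln(f2/f1) + b (f2-f1)) / ln 10
  total <- 0
  for (i in seq_len(length(vf) - 1L)) {
    f1 <- vf[i]; f2 <- vf[i + 1L]
    if (f2 <= f1) next  # vertical jumps contribute nothing
    b <- (vt[i + 1L] - vt[i]) / (f2 - f1)
    a <- vt[i] - b * f1
    total <- total + (a * log(f2 / f1) + b * (f2 - f1)) / log(10)
  }
  total
}

#' Semilogarithmic AUC and adjusted logAUC
#'
#' `log_auc` integrates the ROC curve against a logarithmic false-positive
#' axis over `[lambda, 1]`, normalized by `log10(1/lambda)` and expressed
#' in percent; the log axis weights early enrichment, combining the
#' strengths of AUC and EF1.  `adjusted_log_auc` subtracts the random
#' classifier's area, `100 (1 - lambda) / ln(1/lambda)` percent (about
#' 14.46 for the default `lambda = 0.001`), so zero means random enrichment
#' and positive values mean ligands enrich over decoys.  The integral of
#' the piecewise-linear curve is evaluated in closed form per segment, so
#' the diagonal gives exactly zero.
#'
#' @param curve a `roc_curve` from [roc_points()].
#' @param lambda lower bound of the log-FPR axis, default 0.001.
#' @return Percent area (adjusted or not).
#' @export
adjusted_log_auc <- function(curve, lambda = 0.001) {
  log_auc(curve, lambda) - 100 * (1 - lambda) / log(1 / lambda)
}

#' @rdname adjusted_log_auc
#' @export
log_auc <- function(curve, lambda = 0.001) {
  if (!(lambda > 0 && lambda < 1)) stop("lambda must be in (0, 1)")
  100 * log_auc_integral(curve, lambda) / log10(1 / lambda)
}

split_by_element <- function(elements) split(seq_along(elements), elements)

#' Symmetry-corrected RMSD via optimal assignment
#'
#' Heavy-atom RMSD where atoms of the same element may exchange: within
#' each element the minimum-cost perfect matching under squared distance
#' (the Kuhn-Munkres / Hungarian assignment) replaces the input atom order.
#' Topologically equivalent atoms a symmetry operation relabels — the two
#' carboxylate oxygens, benzene carbons under ring rotation — then no
#' longer inflate the deviation, and the result is never larger than the
#' order-respecting RMSD.
#'
#' @param ref_xyz,probe_xyz n x 3 coordinate matrices of the same molecule.
#' @param ref_elements,probe_elements element symbols per atom; the two
#'   multisets must agree.  Defaults treat all atoms as one element class.
#' @param heavy_only drop hydrogens first (default).
#' @return RMSD in Angstrom.
#' @export
hungarian_rmsd <- function(ref_xyz, probe_xyz,
                           ref_elements = rep("X", nrow(ref_xyz)),
                           probe_elements = rep("X", nrow(probe_xyz)),
                           heavy_only = TRUE) {
  ref_xyz <- as.matrix(ref_xyz)
  probe_xyz <- as.matrix(probe_xyz)
  if (heavy_only) {
    rk <- ref_elements != "H"
    pk <- probe_elements != "H"
    ref_xyz <- ref_xyz[rk, , drop = FALSE]
    ref_elements <- ref_elements[rk]
    probe_xyz <- probe_xyz[pk, , drop = FALSE]
    probe_elements <- probe_elements[pk]
  }
  if (!identical(sort(ref_elements), sort(probe_elements)))
    stop("element multisets of reference and probe differ")
  rg <- split_by_element(ref_elements)
  pg <- split_by_element(probe_elements)
  ss <- 0
  for (el in names(rg)) {
    ri <- rg[[el]]
    pi <- pg[[el]]
    d2 <- outer(seq_along(ri), seq_along(pi), function(a, b) {
      rowSums((ref_xyz[ri[a], , drop = FALSE] - probe_xyz[pi[b], , drop = FALSE])^2)
    })
    ss <- ss + solve_assignment(d2)$cost
  }
  sqrt(ss / nrow(ref_xyz))
}

#' Critical-contact RMSD of a pose
#'
#' Measures whether a docked pose reproduces a small set of
#' pharmacophore-defining reference atoms (e.g. the two carboxylate oxygens
#' and the amide nitrogen a receptor's binding site coordinates).  Each
#' critical reference atom may match any pose atom of the same element; the
#' globally optimal same-element assignment (Hungarian algorithm) defines
#' the RMSD.  A pose lacking enough atoms of a required element has an
#' undefined — not zero — RMSD, returned as `NA`; across a library, report
#' the median over the defined values ([critical_contact_summary()]), which
#' is what makes undefined entries harmless.
#'
#' @param ref_xyz k x 3 critical reference coordinates (k typically 2-5).
#' @param ref_elements element symbol per critical atom.
#' @param pose_xyz,pose_elements the docked pose's atoms.
#' @return RMSD in Angstrom, or `NA` when undefined.
#' @export
critical_contact_rmsd <- function(ref_xyz, ref_elements, pose_xyz,
                                  pose_elements) {
  ref_xyz <- as.matrix(ref_xyz)
  pose_xyz <- as.matrix(pose_xyz)
  if (nrow(ref_xyz) == 0L) stop("critical atom set must not be empty")
  rg <- split_by_element(as.character(ref_elements))
  pg <- split_by_element(as.character(pose_elements))
  ss <- 0
  for (el in names(rg)) {
    ri <- rg[[el]]
    pi <- pg[[el]]
    if (is.null(pi) || length(pi) < length(ri)) return(NA_real_)
    d2 <- outer(seq_along(ri), seq_along(pi), function(a, b) {
      rowSums((ref_xyz[ri[a], , drop = FALSE] - pose_xyz[pi[b], , drop = FALSE])^2)
    })
    ss <- ss + solve_assignment(d2)$cost
  }
  sqrt(ss / nrow(ref_xyz))
}

#' @rdname critical_contact_rmsd
#' @param rmsds vector of per-molecule critical-contact RMSDs, `NA` for
#'   undefined ones.
#' @return `critical_contact_summary`: list with `median` over defined
#'   values, `n_defined`, `n_undefined`.
#' @export
critical_contact_summary <- function(rmsds) {
  ok <- !is.na(rmsds)
  list(median = if (any(ok)) median(rmsds[ok]) else NA_real_,
       n_defined = sum(ok), n_undefined = sum(!ok))
}
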