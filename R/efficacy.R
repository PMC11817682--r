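# The linear efficacy model: maximal signaling responses (Emax, percent of
# the reference agonist) are modeled as an intercept-free weighted sum of
# conformation occupancy fractions, one slope vector per signaling pathway.

#' Pathways modeled
#' @export
PATHWAYS <- c("Gprotein", "barr2")

#' Efficacy tables
#'
#' A tidy table of curated per-ligand, per-pathway efficacy records (percent
#' relative to the reference agonist), possibly with several assay records
#' per key; the model target is the per-key median.
#'
#' @param records data.frame with columns `ligand_id`, `pathway` (one of
#'   `"Gprotein"`, `"barr2"`), `value` (percent), and optionally `assay`.
#' @return an object of class `efficacy_table`.
#' @export
efficacy_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("ligand_id", "pathway", "value")
  if (!all(need %in% names(records))) {
    stopf("efficacy records need columns %s", paste(need, collapse = ", "))
  }
  if (!all(records$pathway %in% PATHWAYS)) {
    stopf("pathway must be one of: %s", paste(PATHWAYS, collapse = ", "))
  }
  if (!all(is.finite(records$value))) stopf("efficacy values must be finite")
  if (!"assay" %in% names(records)) records$assay <- NA_character_
  structure(list(records = records), class = "efficacy_table")
}

#' Read an efficacy table from CSV
#' @param path CSV with columns `ligand_id`, `pathway`, `value`[, `assay`].
#' @return an `efficacy_table`.
#' @export
read_efficacy_table <- function(path) {
  efficacy_table(data.table::fread(path, data.table = FALSE))
}

#' Median efficacy per (ligand, pathway)
#'
#' The modeling target: the sample median over assay records for each key
#' (even record counts give the mean of the two central values).
#'
#' @param table an `efficacy_table`.
#' @param ligands optional ligand subset; every requested ligand must have
#'   at least one record per pathway.
#' @return matrix, rows = ligands (sorted), columns = `Gprotein`, `barr2`.
#' @export
median_efficacy <- function(table, ligands = NULL) {
  r <- table$records
  ligands <- sort(ligands %||% unique(r$ligand_id))
  out <- matrix(NA_real_, length(ligands), length(PATHWAYS),
                dimnames = list(ligands, PATHWAYS))
  for (l in ligands) {
    for (p in PATHWAYS) {
      v <- r$value[r$ligand_id == l & r$pathway == p]
      if (!length(v)) stopf("no efficacy record for ligand %s, pathway %s", l, p)
      out[l, p] <- stats::median(v)
    }
  }
  out
}

# minimum-norm least squares via SVD; rank-deficient designs get the
# pseudoinverse solution (unvisited conformations receive slope 0)
minnorm_fit <- function(F, y, warn = TRUE) {
  sv <- svd(F)
  tol <- max(dim(F)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  if (warn && sum(pos) < ncol(F)) {
    warning(sprintf(
      "rank-deficient design (rank %d < %d conformations); returning the minimum-norm solution",
      sum(pos), ncol(F)), call. = FALSE)
  }
  if (!any(pos)) return(rep(0, ncol(F)))
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

#' Fit regression slopes from fractions to efficacies
#'
#' Intercept-free ordinary least squares per pathway: minimizes
#' `sum_l (e_l - sum_n beta_n f_{l,n})^2`. Because fractions sum to one an
#' intercept would be confounded with a constant shift of all slopes, so
#' none is included. Rank-deficient designs (routine when ligands are fewer
#' than conformations) return the minimum-norm solution with a warning.
#'
#' @param fractions matrix of occupancy fractions, rows = training ligands.
#' @param efficacy matrix of target efficacies with rownames matching
#'   `fractions` and columns `Gprotein`, `barr2` (or a numeric vector for a
#'   single pathway).
#' @param warn emit the rank-deficiency warning (default TRUE).
#' @return matrix of slopes, rows = conformations, columns = pathways (or a
#'   numeric vector if `efficacy` was a vector).
#' @export
fit_slopes <- function(fractions, efficacy, warn = TRUE) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 2L) stopf("need at least 2 training ligands")
  if (is.null(dim(efficacy))) {
    if (length(efficacy) != nrow(fractions)) {
      stopf("efficacy length must match the number of training ligands")
    }
    return(minnorm_fit(fractions, as.numeric(efficacy), warn = warn))
  }
  efficacy <- as.matrix(efficacy)
  if (!is.null(rownames(efficacy)) && !is.null(rownames(fractions))) {
    efficacy <- efficacy[rownames(fractions), , drop = FALSE]
  }
  out <- apply(efficacy, 2L, function(y) minnorm_fit(fractions, y, warn = warn))
  rownames(out) <- colnames(fractions)
  out
}

#' Predict efficacy from a fraction row
#'
#' @param f_row occupancy fraction vector of one ligand.
#' @param slopes slope vector (one pathway) or matrix (columns = pathways).
#' @return scalar or named vector of predicted efficacies (percent).
#' @export
predict_efficacy <- function(f_row, slopes) {
  if (is.null(dim(slopes))) {
    if (length(f_row) != length(slopes)) stopf("fraction/slope length mismatch")
    return(sum(f_row * slopes))
  }
  if (length(f_row) != nrow(slopes)) stopf("fraction/slope length mismatch")
  drop(crossprod(slopes, f_row))
}

#' Prediction accuracy metrics
#'
#' @param predicted,observed numeric vectors (matched order, length >= 2).
#' @return named list: `mae`, `rmse`, `r2` (`r2` is `NaN` with a warning
#'   when the observed values have zero variance).
#' @export
evaluate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stopf("length mismatch")
  if (length(observed) < 2L) stopf("need at least 2 ligands")
  err <- predicted - observed
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) {
    warning("observed values have zero variance; R^2 undefined", call. = FALSE)
    NaN
  } else 1 - sum(err^2) / ss_tot
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), r2 = r2)
}
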