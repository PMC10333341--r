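# ---- Eigenvector centrality over the ROI correlation network ---------------

#' Build the shifted correlation adjacency matrix
#'
#' Entry (i, j) is the Pearson correlation between ROI i and ROI j series
#' plus 1, so all entries lie in [0, 2] and the matrix is elementwise
#' positive (diagonal 2). The +1 shift makes the leading eigenvector real
#' and, by Perron-Frobenius, strictly positive; centralities are invariant
#' to any positive rescaling of the matrix, so this convention and the
#' (1 + r) / 2 variant give identical centrality vectors.
#'
#' @param cleaned ROI x time numeric matrix (>= 3 time points, no constant
#'   rows, no missing values).
#' @return Symmetric n x n matrix of class `ec_adjacency`.
#' @export
build_adjacency <- function(cleaned) {
  cleaned <- as.matrix(cleaned)
  if (ncol(cleaned) < 3L) stop("need at least 3 time points")
  if (anyNA(cleaned)) stop("cleaned matrix contains missing values")
  sds <- apply(cleaned, 1, stats::sd)
  if (any(sds == 0))
    stop("constant ROI series (zero variance) in row(s): ",
         paste(which(sds == 0), collapse = ", "))
  adj <- stats::cor(t(cleaned)) + 1
  adj <- (adj + t(adj)) / 2          # enforce exact symmetry
  diag(adj) <- 2
  class(adj) <- c("ec_adjacency", "matrix", "array")
  adj
}

#' Eigenvector centrality by power iteration
#'
#' Starting from the uniform vector 1/sqrt(n), repeatedly applies the
#' adjacency and renormalizes until the successive-iterate sup-norm change
#' drops below `tol`. For an elementwise-positive matrix this converges to
#' the Perron vector: the unit-norm, strictly positive eigenvector of the
#' largest eigenvalue. The eigenvalue is reported as the Rayleigh quotient.
#'
#' @param adj Symmetric non-negative matrix (e.g. from [build_adjacency()]).
#' @param tol Convergence tolerance on the sup-norm of successive iterates.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return List of class `ec_vector`: `ec` (unit Euclidean norm, positive),
#'   `eigenvalue`, `iterations`.
#' @export
eigenvector_centrality <- function(adj, tol = 1e-12, max_iter = 10000L) {
  adj <- unclass(adj)
  n <- nrow(adj)
  if (ncol(adj) != n) stop("adjacency must be square")
  if (max(abs(adj - t(adj))) > 1e-8) stop("adjacency must be symmetric")
  if (any(adj < 0)) stop("adjacency must be non-negative")
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    w <- drop(adj %*% v)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("adjacency annihilated the iterate (zero matrix?)")
    w <- w / nrm
    delta <- max(abs(w - v))
    v <- w
    if (delta < tol) {
      if (any(v < 0)) v <- -v        # fix sign to the positive Perron vector
      lambda <- drop(crossprod(v, adj %*% v))
      return(structure(list(ec = v, eigenvalue = lambda, iterations = it),
                       class = "ec_vector"))
    }
  }
  stop("power iteration did not converge in ", max_iter,
       " iterations (last delta ", format(delta, digits = 3), ")")
}

#' Per-subject eigenvector centrality table
#'
#' Computes one centrality vector per subject (adjacency build + power
#' iteration) and assembles a subjects x ROI table with the group label.
#'
#' @param subjects Named list of cleaned ROI x time matrices (names are
#'   subject ids), or a list of `subject_timeseries` objects whose `data`
#'   entry is used as-is (no preprocessing is applied here).
#' @param phenotypes Data frame with `subject_id` and `ptsd` columns
#'   (0/1 or logical); rows are matched to `subjects` by id.
#' @return An `ec_table`: data frame with `subject_id`, `group`
#'   (`"case"` / `"control"`), and `roi_0 ... roi_{n-1}` columns. The
#'   per-ROI group means are attached as attribute `group_means`.
#' @export
ec_table <- function(subjects, phenotypes) {
  if (is.null(names(subjects)))
    names(subjects) <- paste0("S", sprintf("%03d", seq_along(subjects)))
  failures <- character(0)
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    m <- if (is.list(s) && !is.null(s$data)) s$data else s
    ec <- tryCatch(eigenvector_centrality(build_adjacency(m))$ec,
                   error = function(e) e)
    if (inherits(ec, "error")) {
      failures <- c(failures,
                    paste0(names(subjects)[i], ": ", conditionMessage(ec)))
    } else rows[[i]] <- ec
  }
  if (length(failures))
    stop("centrality failed for ", length(failures), " subject(s):\n  ",
         paste(failures, collapse = "\n  "))
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("roi_", seq_len(ncol(mat)) - 1L)
  ids <- names(subjects)
  ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  if (anyNA(ph$subject_id))
    stop("phenotype rows missing for: ",
         paste(ids[is.na(ph$subject_id)], collapse = ", "))
  group <- ifelse(as.logical(ph$ptsd), "case", "control")
  out <- data.frame(subject_id = ids, group = group, mat,
                    stringsAsFactors = FALSE)
  gm <- rbind(case = colMeans(mat[group == "case", , drop = FALSE]),
              control = colMeans(mat[group == "control", , drop = FALSE]))
  attr(out, "group_means") <- gm
  class(out) <- c("ec_table", "data.frame")
  out
}

#' Extract the ROI value matrix from an `ec_table`
#' @param ec An `ec_table`.
#' @return Numeric subjects x ROI matrix.
#' @export
ec_matrix <- function(ec) {
  roi_cols <- grep("^roi_", names(ec), value = TRUE)
  as.matrix(as.data.frame(ec)[, roi_cols, drop = FALSE])
}

#' Write / read an `ec_table` as CSV
#' @param ec An `ec_table`.
#' @param path Output path.
#' @export
write_ec_table <- function(ec, path) {
  utils::write.csv(as.data.frame(ec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ec_table
#' @export
read_ec_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("ec_table", "data.frame")
  df
}
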