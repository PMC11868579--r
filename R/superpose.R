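#' Optimal rigid superposition of paired coordinate sets (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto `reference`
#' with reflections excluded (determinant forced to +1), via singular value
#' decomposition of the cross-covariance of the centred coordinates.
#'
#' @param mobile,reference Numeric n x 3 matrices of paired coordinates
#'   (row i of `mobile` pairs with row i of `reference`).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length-3;
#'   the fit maps x to `rotation %*% x + translation`), `rmsd` (Angstrom,
#'   after applying the fit), `n_pairs`, and `degenerate` (`TRUE` when the
#'   point set is rank-deficient, e.g. collinear — the rotation about the
#'   degenerate axis is then arbitrary but still proper).
#' @export
kabsch <- function(mobile, reference) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q))
  if (nrow(P) < 3L) stop("need at least 3 paired points", call. = FALSE)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))          # H = t(Pc) %*% Qc
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  degenerate <- s$d[2L] <= max(s$d[1L], 1) * 1e-10
  if (degenerate) {
    warning("degenerate (rank-deficient) coordinate set; rotation not unique",
            call. = FALSE)
  }
  tr <- as.numeric(cq - R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2L, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, n_pairs = nrow(P),
       degenerate = degenerate)
}

#' Backbone superposition of two structure models
#'
#' Superposes `mobile` onto `reference` over the backbone atoms (N, CA, C,
#' O) of paired residues and reports the post-fit RMSD. Residues missing
#' any of the four backbone atoms in either model are dropped from the
#' pairing with a warning.
#'
#' @param mobile,reference `structure_model` objects.
#' @param pairing Data frame with columns `mobile_chain`, `mobile_resno`,
#'   `ref_chain`, `ref_resno`; `NULL` (default) pairs residues sharing
#'   (chain, residue number) in both models.
#' @return A `superposition`: list with `rotation`, `translation`, `rmsd`,
#'   `n_pairs` (residue pairs used), `n_atoms`, `degenerate`.
#' @export
superpose_backbone <- function(mobile, reference, pairing = NULL) {
  if (is.null(pairing)) {
    mk <- backbone_residue_keys(mobile)
    rk <- backbone_residue_keys(reference)
    common <- intersect(mk, rk)
    pairing <- data.frame(
      mobile_chain = sub("\r.*", "", common),
      mobile_resno = as.integer(sub(".*\r", "", common)),
      ref_chain = sub("\r.*", "", common),
      ref_resno = as.integer(sub(".*\r", "", common)),
      stringsAsFactors = FALSE
    )
  }
  bb <- c("N", "CA", "C", "O")
  get_bb <- function(model, chain, resno) {
    a <- model$atoms
    sel <- !a$is_hetero & a$chain == chain & a$resno == resno & a$name %in% bb
    sub <- a[sel, , drop = FALSE]
    if (nrow(sub) < 4L || !all(bb %in% sub$name)) return(NULL)
    sub <- sub[match(bb, sub$name), , drop = FALSE]
    as.matrix(sub[, c("x", "y", "z")])
  }
  P <- list(); Q <- list(); used <- 0L; dropped <- 0L
  for (i in seq_len(nrow(pairing))) {
    pm <- get_bb(mobile, pairing$mobile_chain[i], pairing$mobile_resno[i])
    pr <- get_bb(reference, pairing$ref_chain[i], pairing$ref_resno[i])
    if (is.null(pm) || is.null(pr)) {
      dropped <- dropped + 1L
      next
    }
    used <- used + 1L
    P[[used]] <- pm
    Q[[used]] <- pr
  }
  if (dropped > 0L) {
    warning(sprintf("%d residue pair(s) dropped: incomplete backbone", dropped),
            call. = FALSE)
  }
  if (used < 3L) {
    stop("insufficient pairs: need >= 3 residue pairs with complete backbone",
         call. = FALSE)
  }
  fit <- kabsch(do.call(rbind, P), do.call(rbind, Q))
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_pairs = used, n_atoms = fit$n_pairs,
                 degenerate = fit$degenerate),
            class = "superposition")
}

# every protein residue with at least one backbone atom; completeness is
# checked (and incomplete residues dropped, with a warning) at pairing time
backbone_residue_keys <- function(model) {
  a <- model$atoms
  a <- a[!a$is_hetero & a$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  unique(paste(a$chain, a$resno, sep = "\r"))
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d residue pairs (%d atoms), rmsd %.3f Angstrom\n",
              x$n_pairs, x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to all atoms of a structure model
#'
#' @param model A `structure_model`.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return The transformed `structure_model`.
#' @export
transform_structure <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(rotation), 2L, translation, "+")
  model$atoms$x <- new[, 1L]
  model$atoms$y <- new[, 2L]
  model$atoms$z <- new[, 3L]
  model
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis Length-3 direction (need not be normalised).
#' @param angle Rotation angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
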