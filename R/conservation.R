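#' Construct a reference-anchored multiple sequence alignment object
#'
#' @param ids Character vector of sequence identifiers (unique).
#' @param seqs Character vector of aligned sequences, equal lengths, gap
#'   character `-`. Stored uppercase.
#' @param reference_id Identifier of the reference sequence (the sequence
#'   whose residue numbering anchors site definitions).
#' @return An `msa_alignment` object.
#' @export
alignment <- function(ids, seqs, reference_id) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must all have equal length", call. = FALSE)
  }
  if (!reference_id %in% ids) {
    stop(sprintf("reference_id '%s' not present in alignment", reference_id),
         call. = FALSE)
  }
  structure(list(ids = ids, seqs = seqs, reference_id = reference_id),
            class = "msa_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (equal-length records).
#' @param reference_id Reference record id; default: the first record.
#' @return An `msa_alignment`; see [alignment()].
#' @export
read_alignment <- function(path, reference_id = NULL) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- names(recs)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  if (is.null(reference_id)) reference_id <- ids[1L]
  alignment(ids, seqs, reference_id)
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("msa_alignment: %d sequences x %d columns (reference '%s')\n",
              length(x$ids), nchar(x$seqs[1L]), x$reference_id))
  invisible(x)
}

aln_chars <- function(aln, id) {
  strsplit(aln$seqs[match(id, aln$ids)], "", fixed = TRUE)[[1L]]
}

#' Map ungapped reference positions to alignment columns
#'
#' @param aln An `msa_alignment`.
#' @return Integer vector: element `i` is the 1-based alignment column
#'   holding ungapped reference position `i`.
#' @export
map_reference_positions <- function(aln) {
  ref <- aln_chars(aln, aln$reference_id)
  cols <- which(ref != "-")
  if (length(cols) == 0L) {
    stop("reference sequence is all gaps", call. = FALSE)
  }
  cols
}

#' Percent sequence identity of an ortholog to the reference
#'
#' Identity is reference-anchored: by default every column where the
#' reference is non-gap is counted, and an ortholog gap at a counted column
#' scores as a mismatch. The alternative `"pairwise"` rule additionally
#' drops ortholog-gap columns from the denominator. `X` never matches,
#' including itself; matching is case-insensitive.
#'
#' @param aln An `msa_alignment`.
#' @param ortholog_id Identifier of the compared record.
#' @param columns Optional integer set of alignment columns to restrict to
#'   (intersected with reference non-gap columns).
#' @param gap_rule `"reference"` (default) or `"pairwise"`; see Details.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(aln, ortholog_id, columns = NULL,
                              gap_rule = c("reference", "pairwise")) {
  gap_rule <- match.arg(gap_rule)
  if (!ortholog_id %in% aln$ids) {
    stop(sprintf("ortholog '%s' not present in alignment", ortholog_id),
         call. = FALSE)
  }
  ref <- aln_chars(aln, aln$reference_id)
  oth <- aln_chars(aln, ortholog_id)
  counted <- which(ref != "-")
  if (!is.null(columns)) {
    columns <- as.integer(columns)
    if (any(columns < 1L | columns > length(ref))) {
      stop("columns outside alignment range", call. = FALSE)
    }
    counted <- intersect(counted, columns)
  }
  if (gap_rule == "pairwise") counted <- counted[oth[counted] != "-"]
  if (length(counted) == 0L) {
    stop("identity undefined: zero counted positions", call. = FALSE)
  }
  match_ok <- ref[counted] == oth[counted] &
    ref[counted] != "X" & oth[counted] != "-"
  100 * sum(match_ok) / length(counted)
}

#' Define a binding site as ungapped reference positions
#'
#' @param name Site label (e.g. `"site2"`, `"cap-site"`).
#' @param positions Residue numbers on the reference numbering scheme.
#' @param offset Constant subtracted from `positions` to convert construct
#'   or author numbering to 1-based ungapped reference positions (default
#'   0: numbering schemes coincide).
#' @return A `site_definition` list.
#' @export
site_definition <- function(name, positions, offset = 0) {
  pos <- as.integer(positions) - as.integer(offset)
  if (any(pos < 1L)) {
    stop("site positions must be >= 1 after offset correction", call. = FALSE)
  }
  structure(list(name = as.character(name), positions = sort(unique(pos))),
            class = "site_definition")
}

#' Per-ortholog global versus site-restricted conservation
#'
#' For every non-reference record, computes global percent identity (all
#' reference-anchored columns) and, per site, identity restricted to the
#' site's columns — the scatter-ready table behind a site-vs-global
#' conservation comparison.
#'
#' @param aln An `msa_alignment`.
#' @param sites List of [site_definition()] objects (may be empty).
#' @inheritParams pairwise_identity
#' @return A `conservation_result` data frame: `id`, `global_identity`, and
#'   one `<site name>_identity` column per site, identities in percent.
#' @export
conservation_profile <- function(aln, sites = list(),
                                 gap_rule = c("reference", "pairwise")) {
  gap_rule <- match.arg(gap_rule)
  if (inherits(sites, "site_definition")) sites <- list(sites)
  pos2col <- map_reference_positions(aln)
  site_cols <- lapply(sites, function(s) {
    if (any(s$positions > length(pos2col))) {
      bad <- s$positions[s$positions > length(pos2col)][1L]
      stop(sprintf("site '%s' position %d beyond reference length %d",
                   s$name, bad, length(pos2col)), call. = FALSE)
    }
    pos2col[s$positions]
  })
  others <- setdiff(aln$ids, aln$reference_id)
  out <- data.frame(id = others, stringsAsFactors = FALSE)
  out$global_identity <- vapply(others, function(id) {
    pairwise_identity(aln, id, gap_rule = gap_rule)
  }, numeric(1))
  for (j in seq_along(sites)) {
    out[[paste0(sites[[j]]$name, "_identity")]] <- vapply(others, function(id) {
      pairwise_identity(aln, id, columns = site_cols[[j]], gap_rule = gap_rule)
    }, numeric(1))
  }
  rownames(out) <- NULL
  class(out) <- c("conservation_result", "data.frame")
  out
}

#' Scatter plot of site versus global conservation
#'
#' One point per ortholog per site (global identity on x, site identity on
#' y) with the identity diagonal; points above the diagonal indicate sites
#' more conserved than the protein overall.
#'
#' @param x A `conservation_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.conservation_result <- function(x, ...) {
  site_cols <- setdiff(names(x), c("id", "global_identity"))
  if (length(site_cols) == 0L) stop("no site columns to plot", call. = FALSE)
  graphics::plot(NA, xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "global identity (%)", ylab = "site identity (%)", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  for (j in seq_along(site_cols)) {
    graphics::points(x$global_identity, x[[site_cols[j]]], pch = 19, col = j + 1)
  }
  graphics::legend("bottomright", legend = sub("_identity$", "", site_cols),
                   col = seq_along(site_cols) + 1, pch = 19, bty = "n")
  invisible(x)
}
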