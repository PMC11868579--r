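#' Define a binding site as the k protein residues closest to a ligand
#'
#' Ranks protein residues by the minimum heavy-atom-to-heavy-atom Euclidean
#' distance to the selected ligand and returns the `k` nearest. Hydrogens,
#' waters (`HOH`) and other hetero residues are excluded from the protein
#' side. With two protein copies in the asymmetric unit the site is defined
#' on a single chain: by default the chain of the protein atom nearest the
#' ligand, overridable via `chain`.
#'
#' @param model A `structure_model`.
#' @param ligand A [ligand_selection()].
#' @param k Site size: number of residues to keep (default 20).
#' @param chain Protein chain to consider; `NULL` (default) selects the
#'   chain of the nearest protein atom.
#' @return A `binding_site`: list with `residues` (data frame `chain`,
#'   `resno`, `resname`, `min_distance`, ascending by distance; ties at the
#'   cut rank broken by chain then residue number), `k`, `ligand`, `chain`.
#' @seealso [contact_residues()] for a distance-cutoff variant.
#' @export
define_site_by_proximity <- function(model, ligand, k = 20, chain = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("k must be a positive integer", call. = FALSE)
  }
  tab <- residue_ligand_distances(model, ligand, chain = chain)
  k <- min(as.integer(k), nrow(tab))
  residues <- tab[seq_len(k), , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(residues = residues, k = k, ligand = ligand,
                 chain = attr(tab, "chain")),
            class = "binding_site")
}

#' Protein residues within a distance cutoff of a ligand
#'
#' Returns every protein residue whose minimum heavy-atom distance to the
#' ligand is `<= cutoff` (the crystallographic contact-shell convention;
#' 4 Angstrom by default).
#'
#' @inheritParams define_site_by_proximity
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return Data frame `chain`, `resno`, `resname`, `min_distance`,
#'   ascending by distance.
#' @export
contact_residues <- function(model, ligand, cutoff = 4.0, chain = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0) {
    stop("cutoff must be a positive distance in Angstrom", call. = FALSE)
  }
  tab <- residue_ligand_distances(model, ligand, chain = chain)
  out <- tab[tab$min_distance <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Full residue-to-ligand minimum heavy-atom distance table for one protein
# chain, sorted ascending with deterministic (chain, resno) tie-breaking.
residue_ligand_distances <- function(model, ligand, chain = NULL) {
  lig <- ligand_atoms(model, ligand)
  prot <- protein_heavy_atoms(model)
  if (nrow(prot) == 0L) {
    stop("model contains no protein residues", call. = FALSE)
  }
  L <- as.matrix(lig[, c("x", "y", "z")])
  P <- as.matrix(prot[, c("x", "y", "z")])
  # squared distances protein-atom x ligand-atom, then per-atom minimum
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * (P %*% t(L))
  dmin_atom <- sqrt(pmax(apply(d2, 1L, min), 0))

  if (is.null(chain)) chain <- prot$chain[which.min(dmin_atom)]
  in_chain <- prot$chain == chain
  if (!any(in_chain)) {
    stop(sprintf("no protein residues on chain '%s'", chain), call. = FALSE)
  }
  key <- paste(prot$chain[in_chain], prot$resno[in_chain], prot$icode[in_chain],
               sep = "\r")
  dmin <- tapply(dmin_atom[in_chain], key, min)
  first <- !duplicated(key)
  tab <- data.frame(
    chain = prot$chain[in_chain][first],
    resno = prot$resno[in_chain][first],
    resname = prot$resname[in_chain][first],
    min_distance = as.numeric(dmin[key[first]]),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$min_distance, tab$chain, tab$resno), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "chain") <- chain
  tab
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("binding_site: %d residues on chain %s nearest %s/%s/%d\n",
              nrow(x$residues), x$chain, x$ligand$chain, x$ligand$resname,
              x$ligand$resno))
  print(x$residues, ...)
  invisible(x)
}

#' Write a binding site or contact table to CSV and/or JSON
#'
#' @param site A `binding_site` or a contact-residue data frame.
#' @param csv,json Output paths; `NULL` skips that format.
#' @return Invisibly, the exported data frame (columns `chain`, `resnum`,
#'   `resname`, `min_distance_angstrom`).
#' @export
write_site <- function(site, csv = NULL, json = NULL) {
  tab <- if (inherits(site, "binding_site")) site$residues else site
  out <- data.frame(chain = tab$chain, resnum = tab$resno,
                    resname = tab$resname,
                    min_distance_angstrom = tab$min_distance)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(out, json, dataframe = "rows", digits = NA)
  }
  invisible(out)
}
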