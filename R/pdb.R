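#' Parse a PDB-format coordinate block
#'
#' Reads fixed-column `ATOM`/`HETATM` records from PDB-format text into a
#' `structure_model`. Alternate locations are resolved to a single atom per
#' (chain, residue, insertion code, atom name): the highest-occupancy
#' conformer is kept, ties prefer altloc `"A"`, then first occurrence.
#' Waters are retained but carry residue name `HOH` so downstream site
#' operations can exclude them.
#'
#' @param text PDB-format content: a single string (possibly with embedded
#'   newlines) or a character vector of lines.
#' @param identifier Label stored on the model (default `"structure"`).
#' @param resolve_altloc Collapse alternate locations (default `TRUE`).
#' @return A `structure_model`: a list with `atoms` (data frame with columns
#'   `serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `icode`,
#'   `x`, `y`, `z`, `occupancy`, `element`, `is_hetero`) and `identifier`.
#' @examples
#' pdb <- paste(
#'   "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
#'   sep = "\n")
#' m <- parse_structure(pdb)
#' nrow(m$atoms)
#' @export
parse_structure <- function(text, identifier = "structure", resolve_altloc = TRUE) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  is_coord <- grepl("^(ATOM  |HETATM)", text)
  if (!any(is_coord)) {
    stop("empty structure: no ATOM or HETATM records found", call. = FALSE)
  }
  lineno <- which(is_coord)
  lines <- formatC(text[is_coord], width = 80L, flag = "-")

  num_field <- function(from, to, what, required = TRUE) {
    raw <- trimws(substr(lines, from, to))
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & (required | nzchar(raw))
    if (any(bad)) {
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, lineno[which(bad)[1L]], raw[which(bad)[1L]]),
           call. = FALSE)
    }
    val
  }

  occ <- trimws(substr(lines, 55, 60))
  occ_val <- suppressWarnings(as.numeric(occ))
  occ_val[!nzchar(occ)] <- 1.0
  if (anyNA(occ_val)) {
    stop(sprintf("malformed occupancy field at line %d",
                 lineno[which(is.na(occ_val))[1L]]), call. = FALSE)
  }

  atoms <- data.frame(
    serial    = num_field(7, 11, "serial"),
    name      = trimws(substr(lines, 13, 16)),
    altloc    = substr(lines, 17, 17),
    resname   = trimws(substr(lines, 18, 20)),
    chain     = substr(lines, 22, 22),
    resno     = as.integer(num_field(23, 26, "residue number")),
    icode     = substr(lines, 27, 27),
    x         = num_field(31, 38, "x coordinate"),
    y         = num_field(39, 46, "y coordinate"),
    z         = num_field(47, 54, "z coordinate"),
    occupancy = occ_val,
    element   = trimws(substr(lines, 77, 78)),
    is_hetero = grepl("^HETATM", lines),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates encountered", call. = FALSE)
  }
  blank <- !nzchar(atoms$element)
  if (any(blank)) atoms$element[blank] <- infer_element(atoms$name[blank])
  atoms$element <- toupper(atoms$element)

  if (resolve_altloc) atoms <- resolve_altlocs(atoms)
  new_structure_model(atoms, identifier)
}

#' Read a PDB file into a structure model
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_structure
#' @return A `structure_model`; see [parse_structure()].
#' @export
read_structure <- function(path, identifier = basename(path), resolve_altloc = TRUE) {
  parse_structure(readLines(path, warn = FALSE), identifier, resolve_altloc)
}

# Element inference when columns 77-78 are blank: strip digits and primes,
# take the leading letter. Covers C/N/O/S/P/H and deuterium in protein and
# organic-ligand records; two-letter metals must carry an element field.
infer_element <- function(name) {
  core <- gsub("[0-9']", "", name)
  el <- toupper(substr(core, 1L, 1L))
  el[el == "D"] <- "H"
  el[!nzchar(el)] <- "X"
  el
}

resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- atoms$occupancy[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1L) {
      a <- best[atoms$altloc[best] == "A"]
      best <- if (length(a)) a[1L] else best[1L]
    }
    best
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

new_structure_model <- function(atoms, identifier) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, identifier = identifier),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model '%s': %d atoms (%d hetero), chains %s\n",
              x$identifier, nrow(a), sum(a$is_hetero),
              paste(sort(unique(a$chain)), collapse = ",")))
  invisible(x)
}

#' Identify one hetero residue as the reference ligand
#'
#' @param chain Chain identifier (single character).
#' @param resname Three-letter residue name of the ligand.
#' @param resno Residue number as printed in the coordinate file.
#' @return A `ligand_selection` list.
#' @export
ligand_selection <- function(chain, resname, resno) {
  structure(list(chain = as.character(chain), resname = as.character(resname),
                 resno = as.integer(resno)),
            class = "ligand_selection")
}

# Heavy atoms of the selected ligand residue; errors if the selection does
# not resolve to at least one heavy atom.
ligand_atoms <- function(model, ligand) {
  a <- model$atoms
  sel <- a$chain == ligand$chain & a$resname == ligand$resname &
    a$resno == ligand$resno & !(a$element %in% c("H", "D"))
  if (!any(sel)) {
    stop(sprintf("ligand %s/%s/%d not found (or has no heavy atoms) in '%s'",
                 ligand$chain, ligand$resname, ligand$resno, model$identifier),
         call. = FALSE)
  }
  a[sel, , drop = FALSE]
}

# Protein-side heavy atoms: non-hetero, non-water, non-hydrogen.
protein_heavy_atoms <- function(model) {
  a <- model$atoms
  a[!a$is_hetero & a$resname != "HOH" & !(a$element %in% c("H", "D")), ,
    drop = FALSE]
}

#' Serialise a structure model back to PDB-format text
#'
#' @param model A `structure_model`.
#' @return Character vector of fixed-column PDB lines (terminated by `END`).
#' @export
write_pdb <- function(model) {
  a <- model$atoms
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  # atom names up to 3 characters start in column 14 (standard convention)
  nm <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial, nm, a$altloc, a$resname, a$chain, a$resno,
                   a$icode, a$x, a$y, a$z, a$occupancy, 0, a$element)
  c(lines, "END")
}
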