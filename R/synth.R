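AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Generate a seeded synthetic ortholog family
#'
#' Emulates an ortholog alignment in which binding-site columns are more
#' conserved than the background: a random reference sequence is mutated
#' per position, per ortholog, at rate `p_site` inside the site and
#' `p_global` elsewhere, substitutions drawn uniformly from the 19
#' alternative residues. With `indel_prob > 0`, ortholog positions are
#' deleted (gap `-`) at that rate, keeping the alignment columnar. The
#' generator is a pure function of its arguments and seed.
#'
#' @param length Reference sequence length (default 217, a typical
#'   cap-binding initiation-factor length).
#' @param n_orthologs Number of non-reference sequences (default 30).
#' @param p_global Per-position substitution probability outside the site
#'   (default 0.12, mammal-to-vertebrate ortholog territory).
#' @param p_site Per-position substitution probability inside the site
#'   (default 0.02); must satisfy `p_site <= p_global`.
#' @param site_positions Ungapped reference positions of the site; default:
#'   20 positions drawn once from the seeded stream.
#' @param indel_prob Per-position deletion probability (default 0).
#' @param seed Integer seed (required; the spec of the family).
#' @return List: `alignment` (an [alignment()], reference id
#'   `"reference"`), `site` (a [site_definition()] named `"site"`),
#'   `truth` (list: `site_positions`, `p_global`, `p_site`, `n_subs` per
#'   ortholog), and `fasta` (aligned FASTA text lines).
#' @export
generate_ortholog_family <- function(length = 217, n_orthologs = 30,
                                     p_global = 0.12, p_site = 0.02,
                                     site_positions = NULL, indel_prob = 0,
                                     seed) {
  if (p_global < 0 || p_global > 1 || p_site < 0 || p_site > 1 ||
      indel_prob < 0 || indel_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_site > p_global) {
    stop("conservation-enriched family requires p_site <= p_global",
         call. = FALSE)
  }
  set.seed(seed)
  ref <- sample(AA20, length, replace = TRUE)
  if (is.null(site_positions)) {
    site_positions <- sort(sample.int(length, min(20L, length)))
  }
  site_positions <- as.integer(site_positions)
  p_vec <- rep(p_global, length)
  p_vec[site_positions] <- p_site

  ids <- c("reference", sprintf("ortholog_%02d", seq_len(n_orthologs)))
  seqs <- character(n_orthologs + 1L)
  seqs[1L] <- paste(ref, collapse = "")
  n_subs <- integer(n_orthologs)
  for (i in seq_len(n_orthologs)) {
    s <- ref
    mut <- stats::runif(length) < p_vec
    if (any(mut)) {
      s[mut] <- vapply(which(mut), function(j) {
        sample(setdiff(AA20, ref[j]), 1L)
      }, character(1))
    }
    if (indel_prob > 0) {
      del <- stats::runif(length) < indel_prob
      s[del] <- "-"
      mut <- mut | del
    }
    n_subs[i] <- sum(mut)
    seqs[i + 1L] <- paste(s, collapse = "")
  }
  aln <- alignment(ids, seqs, "reference")
  fasta <- as.vector(rbind(paste0(">", ids), seqs))
  list(alignment = aln,
       site = site_definition("site", site_positions),
       truth = list(site_positions = site_positions, p_global = p_global,
                    p_site = p_site, n_subs = n_subs),
       fasta = fasta)
}

#' Generate a seeded synthetic CPMG screening deck
#'
#' Plants exactly `n_binders` fragments whose attenuation ratios fall below
#' `tau - margin` in a library of `n_library`, the remainder above
#' `tau + margin`; a fraction of binders is cap-site-competable and gets a
#' recovering post-competitor ratio. Fragments are grouped into cocktails
#' of 4. Ground truth is emitted alongside so downstream tests never
#' re-derive it from the generated intensities.
#'
#' @param n_library Library size (default 1371).
#' @param n_binders Number of planted binders (default 50).
#' @param tau Binder threshold the deck is separated around (default 0.8).
#' @param margin Half-width of the excluded band around `tau`
#'   (default 0.05); binder ratios are drawn from
#'   `[rho_min, tau - margin]`, non-binders from `[tau + margin, 1.02]`.
#' @param rho_min Lower bound of binder ratios (default 0.1).
#' @param frac_site1 Fraction of binders that are cap-site-competable
#'   (default 0.2).
#' @param allow_overlap Permit `margin <= 0` (overlapping distributions);
#'   default `FALSE`.
#' @param seed Integer seed.
#' @return List: `records` (data frame `fragment_id`, `cocktail_id`,
#'   `i_ref`, `i_protein`, `i_competitor`) and `truth` (data frame
#'   `fragment_id`, `is_binder`, `site1`, `rho`).
#' @export
generate_screen_deck <- function(n_library = 1371, n_binders = 50, tau = 0.8,
                                 margin = 0.05, rho_min = 0.1,
                                 frac_site1 = 0.2, allow_overlap = FALSE,
                                 seed) {
  if (n_binders > n_library) stop("n_binders must be <= n_library", call. = FALSE)
  if (margin <= 0 && !allow_overlap) {
    stop("binder and non-binder ratio ranges overlap; set allow_overlap = TRUE",
         call. = FALSE)
  }
  set.seed(seed)
  n <- n_library
  fragment_id <- sprintf("F%04d", seq_len(n))
  cocktail_id <- sprintf("C%04d", ceiling(seq_len(n) / 4))
  binder <- logical(n)
  binder[sample.int(n, n_binders)] <- TRUE
  rho <- numeric(n)
  rho[binder] <- stats::runif(n_binders, rho_min, tau - margin)
  rho[!binder] <- stats::runif(n - n_binders, tau + margin, 1.02)
  site1 <- logical(n)
  idx_b <- which(binder)
  n_site1 <- round(frac_site1 * n_binders)
  if (n_site1 > 0) site1[sample(idx_b, n_site1)] <- TRUE

  i_ref <- stats::runif(n, 80, 120)
  i_protein <- rho * i_ref
  rho_comp <- rep(NA_real_, n)
  rho_comp[binder & site1] <- pmin(1, rho[binder & site1] +
                                     stats::runif(sum(binder & site1), 0.25, 0.45))
  rho_comp[binder & !site1] <- pmin(1, rho[binder & !site1] +
                                      stats::runif(sum(binder & !site1), 0, 0.05))
  i_competitor <- rho_comp * i_ref
  list(
    records = data.frame(fragment_id = fragment_id, cocktail_id = cocktail_id,
                         i_ref = i_ref, i_protein = i_protein,
                         i_competitor = i_competitor,
                         stringsAsFactors = FALSE),
    truth = data.frame(fragment_id = fragment_id, is_binder = binder,
                       site1 = site1, rho = rho, stringsAsFactors = FALSE)
  )
}

#' Generate a seeded toy protein-ligand structure with known geometry
#'
#' Builds a small protein (four-atom backbone N, CA, C, O plus a CB heavy
#' side-chain atom per residue) in a chosen geometry with one `HETATM`
#' ligand residue, writes parseable PDB text, and emits the true
#' residue-to-ligand minimum heavy-atom distance table computed directly
#' from the generating coordinates — so downstream site definitions can be
#' checked against generator truth rather than re-derived.
#'
#' @param n_residues Number of protein residues (default 12).
#' @param geometry `"line"` (CA positions spaced along x), `"helix"`
#'   (ideal alpha-helix CA trace), or `"sphere"` (seeded random positions
#'   in a shell).
#' @param spacing CA-CA spacing in Angstrom for `"line"` (default 3.8).
#' @param ligand_center Length-3 position of the ligand centroid (default
#'   origin).
#' @param ligand_n_atoms Number of ligand heavy atoms (default 3).
#' @param seed Integer seed.
#' @return List: `model` (a `structure_model`), `pdb` (text lines),
#'   `truth` (data frame `chain`, `resno`, `resname`, `min_distance`,
#'   sorted ascending).
#' @export
generate_toy_structure <- function(n_residues = 12, geometry = c("line", "helix", "sphere"),
                                   spacing = 3.8, ligand_center = c(0, 0, 0),
                                   ligand_n_atoms = 3, seed) {
  geometry <- match.arg(geometry)
  set.seed(seed)
  ca <- switch(geometry,
    line = cbind(seq_len(n_residues) * spacing, 0, 0),
    helix = {
      t <- seq_len(n_residues) * 100 * pi / 180   # 100 deg per residue
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * seq_len(n_residues))
    },
    sphere = {
      u <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * stats::runif(n_residues, 6, 14)
      sweep(u, 2L, c(0, 0, 0), "+")
    }
  )
  resnames <- sample(c("ALA", "GLY", "LEU", "SER", "VAL", "THR"),
                     n_residues, replace = TRUE)
  # local backbone offsets around each CA (rigid, arbitrary but fixed)
  offs <- list(N = c(-1.33, 0.50, 0.00), CA = c(0, 0, 0),
               C = c(1.33, 0.50, 0.00), O = c(1.35, 1.73, 0.00),
               CB = c(-0.30, -1.20, 0.95))
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    do.call(rbind, lapply(names(offs), function(nm) {
      p <- ca[i, ] + offs[[nm]]
      data.frame(name = nm, resname = resnames[i], chain = "A",
                 resno = i, x = p[1], y = p[2], z = p[3],
                 element = substr(nm, 1, 1), is_hetero = FALSE,
                 stringsAsFactors = FALSE)
    }))
  }))
  lig_xyz <- matrix(rep(ligand_center, each = ligand_n_atoms), ncol = 3) +
    matrix(stats::rnorm(3 * ligand_n_atoms, 0, 0.4), ncol = 3)
  lig <- data.frame(name = paste0("C", seq_len(ligand_n_atoms)),
                    resname = "LIG", chain = "L", resno = 1,
                    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                    element = "C", is_hetero = TRUE, stringsAsFactors = FALSE)
  atoms <- rbind(atoms, lig)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$altloc <- ""
  atoms$icode <- ""
  atoms$occupancy <- 1.0
  atoms <- atoms[, c("serial", "name", "altloc", "resname", "chain", "resno",
                     "icode", "x", "y", "z", "occupancy", "element",
                     "is_hetero")]
  model <- new_structure_model(atoms, sprintf("toy_%s_seed%d", geometry, seed))

  # generator-side truth: min distance of each residue's heavy atoms to the
  # ligand heavy atoms, computed from the raw coordinates
  truth <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    res <- atoms[atoms$resno == i & !atoms$is_hetero, c("x", "y", "z")]
    d <- apply(as.matrix(res), 1L, function(p) {
      min(sqrt(colSums((t(lig_xyz) - p)^2)))
    })
    data.frame(chain = "A", resno = i, resname = resnames[i],
               min_distance = min(d), stringsAsFactors = FALSE)
  }))
  truth <- truth[order(truth$min_distance, truth$chain, truth$resno), ]
  rownames(truth) <- NULL
  list(model = model, pdb = write_pdb(model), truth = truth)
}
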