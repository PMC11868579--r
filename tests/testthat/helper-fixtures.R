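# Hand-assembled fixed-column PDB fixtures and small builders used across
# the structure tests.

pdb_line <- function(record = "ATOM", serial, name, resname, chain, resno,
                     x, y, z, occ = 1.00, element = NULL, altloc = " ") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, x, y, z, occ, 0,
          element)
}

# single-atom residues at given x offsets from a ligand atom at the origin
toy_pocket_pdb <- function(xs, ligand_xyz = c(0, 0, 0)) {
  lines <- vapply(seq_along(xs), function(i) {
    pdb_line("ATOM", i, "CA", "GLY", "A", i, xs[i], 0, 0)
  }, character(1))
  c(lines,
    pdb_line("HETATM", length(xs) + 1L, "C1", "LIG", "L", 1,
             ligand_xyz[1], ligand_xyz[2], ligand_xyz[3]))
}

toy_ligand <- function() ligand_selection("L", "LIG", 1)

# small alignment builders
toy_alignment <- function() {
  alignment(c("ref", "orthA", "orthB"),
            c("ACDEFG", "ACDEYG", "ACDEFG"),
            "ref")
}
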