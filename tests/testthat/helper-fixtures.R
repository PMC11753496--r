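# In-code fixtures shared across test files.

write_trace_csv <- function(lines, unit = "C_per_min") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(sprintf("# condition_unit: %s", unit),
               "sample,condition,x,y", lines), path)
  path
}

write_spectrum_csv <- function(wl, inten) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("wavelength,intensity",
               paste(wl, inten, sep = ",")), path)
  path
}

# minimal hand-built PDB: one chain, arbitrary per-atom B/occupancy/altloc
pdb_atom_line <- function(serial, name, resno, b, occ = 1, alt = "",
                          chain = "A", resname = "ALA", x = resno * 2,
                          y = 0, z = 0, element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b, element)
}

write_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

# three residues, all atoms of residue i carrying B = 10 * i
toy_three_residue_pdb <- function() {
  lines <- character(); s <- 0
  for (i in 1:3) {
    for (nm in c("N", "CA", "C", "O")) {
      s <- s + 1
      lines <- c(lines, pdb_atom_line(s, nm, i, b = 10 * i, x = i * 3 + s))
    }
  }
  write_pdb(lines)
}
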