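#' Per-residue B-factor map
#'
#' Ordered map from residue identity (chain, residue number, insertion code)
#' to a per-residue B statistic, with a lineage tag recording how the values
#' were derived: `raw` residue-mean B, `znorm` within-structure z-scores,
#' `averaged` across structures, `diff_signed`/`diff_abs` between variants,
#' `minmax01` rescaled to [0, 1].
#'
#' @param df data.frame with columns `chain`, `resno`, `icode`, `value`
#'   (`icode` optional, defaults to "").
#' @param lineage one of `raw`, `znorm`, `averaged`, `diff_signed`,
#'   `diff_abs`, `minmax01`.
#' @param source character vector of source structure identifiers.
#' @return A `residue_b_map` data.frame sorted by (chain, resno, icode).
#' @export
residue_b_map <- function(df, lineage = "raw", source = character()) {
  lineage <- match.arg(lineage, c("raw", "znorm", "averaged", "diff_signed",
                                  "diff_abs", "minmax01"))
  if (is.null(df$icode)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  df <- df[c("chain", "resno", "icode", "value")]
  df <- df[order(df$chain, df$resno, df$icode), ]
  rownames(df) <- NULL
  structure(df, lineage = lineage, source = source,
            class = c("residue_b_map", "data.frame"))
}

b_keys <- function(map) paste(map$chain, map$resno, map$icode, sep = "|")

#' @export
print.residue_b_map <- function(x, ...) {
  cat(sprintf("Residue B map [%s] from %s: %d residues\n",
              attr(x, "lineage"),
              paste(attr(x, "source"), collapse = "+"), nrow(x)))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Z-normalize a B-factor map within one structure
#'
#' Standardizes residue B values to mean 0 and sample (n-1) standard
#' deviation 1.  This removes the overall-B offset between datasets refined
#' at different resolutions, which is what makes cross-crystal per-residue
#' comparison meaningful.
#'
#' @param map a `residue_b_map`.
#' @return the z-scored map (`lineage = "znorm"`).
#' @export
znorm <- function(map) {
  if (nrow(map) < 3)
    sk_stop("need at least 3 residues to z-normalize", "sk_insufficient_data")
  s <- sd(map$value)
  if (s == 0)
    sk_stop("constant B-factors: degenerate structure", "sk_degenerate_input")
  out <- as.data.frame(map)
  out$value <- (out$value - mean(out$value)) / s
  residue_b_map(out, lineage = "znorm", source = attr(map, "source"))
}

#' Average B-factor maps across structures
#'
#' Per-residue mean over two or more (normalized) maps, restricted to
#' residues modelled in all structures.  Residues dropped from the
#' intersection (for example disordered loop residues lacking electron
#' density in one dataset) are listed in the `dropped` attribute, never
#' imputed.
#'
#' @param maps list of `residue_b_map` objects with compatible chain naming.
#' @return the averaged map (`lineage = "averaged"`); attribute `dropped`
#'   lists residue keys absent from at least one input.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 2)
  keysets <- lapply(maps, b_keys)
  common <- Reduce(intersect, keysets)
  if (!length(common))
    sk_stop("no residues shared by all structures", "sk_empty_intersection")
  dropped <- setdiff(Reduce(union, keysets), common)
  vals <- vapply(maps, function(m) m$value[match(common, b_keys(m))],
                 numeric(length(common)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(common))
  ref <- maps[[1]][match(common, b_keys(maps[[1]])), c("chain", "resno", "icode")]
  ref$value <- rowMeans(vals)
  out <- residue_b_map(ref, lineage = "averaged",
                       source = unlist(lapply(maps, attr, "source")))
  attr(out, "dropped") <- dropped
  out
}

#' Difference two B-factor maps
#'
#' Per-residue `a - b` (signed) or `|a - b|` (absolute) over the residues
#' present in both maps.  Both maps should be at the same lineage stage
#' (typically `znorm` or `averaged`).
#'
#' @param a,b `residue_b_map` objects.
#' @param mode `"signed"` or `"absolute"`.
#' @return the difference map.
#' @export
diff_maps <- function(a, b, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!identical(attr(a, "lineage"), attr(b, "lineage")))
    sk_stop(sprintf("lineage mismatch: %s vs %s",
                    attr(a, "lineage"), attr(b, "lineage")),
            "sk_lineage_error")
  ka <- b_keys(a); kb <- b_keys(b)
  common <- intersect(ka, kb)
  if (!length(common))
    sk_stop("no residues shared by the two maps", "sk_empty_intersection")
  ia <- match(common, ka); ib <- match(common, kb)
  d <- a$value[ia] - b$value[ib]
  if (mode == "absolute") d <- abs(d)
  out <- a[ia, c("chain", "resno", "icode")]
  out$value <- d
  residue_b_map(out,
                lineage = if (mode == "signed") "diff_signed" else "diff_abs",
                source = c(attr(a, "source"), attr(b, "source")))
}

#' Rescale a B-factor map to the unit interval
#'
#' Min-max rescaling `(value - min)/(max - min)`; the minimum maps to 0 and
#' the maximum to 1.  Shift-invariant, so negative inputs (z-scores,
#' differences) are fine.
#'
#' @param map a `residue_b_map` with at least 2 distinct values.
#' @return the rescaled map (`lineage = "minmax01"`).
#' @export
minmax01 <- function(map) {
  rng <- range(map$value)
  if (diff(rng) == 0)
    sk_stop("all values equal: min-max rescaling undefined",
            "sk_degenerate_input")
  out <- as.data.frame(map)
  out$value <- (out$value - rng[1]) / diff(rng)
  residue_b_map(out, lineage = "minmax01", source = attr(map, "source"))
}

#' Write map values into the B column of a PDB file
#'
#' Produces a copy of `structure_path` in which every atom of a mapped
#' residue carries the residue's map value in the B-factor column
#' (fixed-format `%6.2f`), for colouring in molecular graphics.  Atoms of
#' unmapped residues get 0.00; their residue keys are returned.
#'
#' @param structure_path input PDB.
#' @param map a `residue_b_map` whose keys resolve against the structure.
#' @param out_path output PDB path.
#' @return invisibly, list with `written` (atoms rewritten) and `unmapped`
#'   (residue keys present in the structure but absent from the map).
#' @export
write_bfactor_column <- function(structure_path, map, out_path) {
  lines <- readLines(structure_path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  keys <- b_keys(map)
  unmapped <- character()
  written <- 0L
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 66) ln <- formatC(ln, width = 66, flag = "-")
    chain <- substr(ln, 22, 22)
    resno <- as.integer(trimws(substr(ln, 23, 26)))
    icode <- trimws(substr(ln, 27, 27))
    key <- paste(chain, resno, icode, sep = "|")
    j <- match(key, keys)
    val <- if (is.na(j)) {
      unmapped <- c(unmapped, key)
      0
    } else map$value[j]
    substr(ln, 61, 66) <- sprintf("%6.2f", val)
    lines[i] <- ln
    written <- written + 1L
  }
  writeLines(lines, out_path)
  invisible(list(written = written, unmapped = unique(unmapped)))
}
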