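#' Read a long-format fluorescence trace table
#'
#' Canonical input for melt and kinetic analyses: a long (tidy) CSV with
#' header columns `sample`, `condition`, `x`, `y`.  `condition` is a ramp
#' rate in degC/min (melt schema) or a hold temperature in degC (kinetic
#' schema); `x` is temperature in degC or time in seconds; `y` is
#' fluorescence in arbitrary units.  The condition unit is declared once per
#' file in a leading comment line of the form `# condition_unit: C_per_min`
#' (or passed via `unit`).
#'
#' Within each (sample, condition) group rows are sorted by `x` and duplicate
#' `x` values are collapsed to their mean `y`.  Groups with fewer than
#' `min_points` points after collapsing are rejected, since downstream fits
#' need a minimally sampled transition.
#'
#' @param path CSV file path.
#' @param schema `"melt"` or `"kinetic"`; recorded on the result and used to
#'   pick the default condition unit name.
#' @param unit condition unit string; overrides any unit declared in the file.
#' @param min_points minimum points per group (default 8).
#' @return A `trace_table`: a data.frame with columns `sample`, `condition`,
#'   `x`, `y`, sorted within groups, with attributes `condition_unit` and
#'   `schema`.
#' @export
read_trace_table <- function(path, schema = c("melt", "kinetic"), unit = NULL,
                             min_points = 8L) {
  schema <- match.arg(schema)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  unit_lines <- grep("condition_unit", meta, value = TRUE)
  file_unit <- if (length(unit_lines)) {
    trimws(sub(".*condition_unit\\s*:\\s*", "", unit_lines[1]))
  } else NULL
  if (length(unit_lines) > 1) {
    units <- unique(trimws(sub(".*condition_unit\\s*:\\s*", "", unit_lines)))
    if (length(units) > 1)
      sk_stop("condition unit declared more than once with conflicting values",
              "sk_unit_error")
  }
  unit <- unit %||% file_unit %||%
    switch(schema, melt = "C_per_min", kinetic = "C")

  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("sample", "condition", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    sk_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "sk_format_error")
  if (anyNA(df$x))
    sk_stop("NaN/NA values in x are not allowed", "sk_format_error")

  key <- interaction(df$sample, df$condition, drop = TRUE)
  pieces <- lapply(split(df[needed], key), function(g) {
    agg <- aggregate(y ~ x, data = g, FUN = mean)
    agg <- agg[order(agg$x), ]
    data.frame(sample = g$sample[1], condition = g$condition[1],
               x = agg$x, y = agg$y, stringsAsFactors = FALSE)
  })
  too_small <- vapply(pieces, nrow, 1L) < min_points
  if (any(too_small))
    sk_stop(sprintf("group(s) with fewer than %d points: %s", min_points,
                    paste(names(pieces)[too_small], collapse = ", ")),
            "sk_format_error")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, condition_unit = unit, schema = schema,
            class = c("trace_table", "data.frame"))
}

#' Write a trace table
#'
#' Inverse of [read_trace_table()]: writes the condition-unit declaration as
#' a leading comment and the numbers at full precision so that a read-back
#' reproduces the table exactly.
#'
#' @param tab a `trace_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(tab, path) {
  unit <- attr(tab, "condition_unit") %||% "C_per_min"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condition_unit: %s", unit), con)
  fmt <- function(v) {
    if (is.numeric(v)) vapply(v, function(z) format(z, digits = 17), "") else as.character(v)
  }
  writeLines("sample,condition,x,y", con)
  writeLines(paste(fmt(tab$sample), fmt(tab$condition), fmt(tab$x), fmt(tab$y),
                   sep = ","), con)
  invisible(path)
}

#' Read an emission spectrum
#'
#' Two-column CSV (wavelength in nm, intensity in arbitrary units).  Points
#' are sorted by wavelength; negative intensities are clipped to zero with a
#' warning reporting how many were clipped.
#'
#' @param path CSV file path.
#' @return A `spectrum_record` data.frame with columns `wavelength`,
#'   `intensity`.
#' @export
read_spectrum <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    sk_stop("spectrum file must have two columns (wavelength, intensity)",
            "sk_format_error")
  df <- data.frame(wavelength = df[[1]], intensity = df[[2]])
  if (nrow(df) < 3)
    sk_stop("spectrum must have at least 3 points", "sk_format_error")
  df <- df[order(df$wavelength), ]
  rownames(df) <- NULL
  if (diff(range(df$wavelength)) <= 0)
    sk_stop("spectrum wavelength span must be positive", "sk_format_error")
  n_neg <- sum(df$intensity < 0)
  if (n_neg > 0) {
    df$intensity[df$intensity < 0] <- 0
    sk_warn(sprintf("%d negative intensity value(s) clipped to 0", n_neg),
            "sk_clip_warning")
  }
  structure(df, class = c("spectrum_record", "data.frame"))
}

#' Build a spectrum record from vectors
#'
#' @param wavelength nm, will be sorted.
#' @param intensity arbitrary units.
#' @return A `spectrum_record`.
#' @export
spectrum_record <- function(wavelength, intensity) {
  stopifnot(length(wavelength) == length(intensity))
  if (length(wavelength) < 3)
    sk_stop("spectrum must have at least 3 points", "sk_format_error")
  o <- order(wavelength)
  structure(data.frame(wavelength = wavelength[o], intensity = intensity[o]),
            class = c("spectrum_record", "data.frame"))
}

#' Read per-residue B-factors from a PDB file
#'
#' Parses a PDB coordinate file (first model if several) and returns the
#' per-residue mean B-factor over the selected atoms.  Waters and other
#' hetero groups are excluded; hydrogens are excluded from `all_heavy`.
#' Where alternate conformers are present, each atom contributes once via
#' its highest-occupancy conformer (first on ties).
#'
#' @param path PDB file path.
#' @param selection `"all_heavy"` (mean over all heavy protein atoms) or
#'   `"calpha"` (C-alpha atoms only).
#' @return A [residue_b_map()] with lineage `"raw"`.
#' @export
read_structure_b <- function(path, selection = c("all_heavy", "calpha")) {
  selection <- match.arg(selection)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) sk_stop(paste0("PDB parse error: ", conditionMessage(e)),
                                "sk_parse_error"))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (selection == "calpha") {
    at <- at[at$elety == "CA", , drop = FALSE]
  } else {
    at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  }
  if (!nrow(at))
    sk_stop("no protein atoms found in structure", "sk_empty_structure")

  # altloc resolution: one conformer per (chain, resno, icode, atom name)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), akey), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- at$o[idx]
    occ[is.na(occ)] <- 1
    idx[which.max(occ)]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  agg <- aggregate(at$b, by = list(chain = at$chain, resno = at$resno,
                                   icode = at$insert), FUN = mean)
  names(agg)[4] <- "value"
  residue_b_map(agg, lineage = "raw", source = basename(path))
}

#' Run configuration
#'
#' A validated key-value settings object.  Unknown keys are rejected; path
#' settings are resolved to absolute paths at construction time so that no
#' computation starts with an unresolvable output location.
#'
#' @param ... named settings among: `fit_window` (numeric length 2, degC),
#'   `reference_temperature_c` (numeric), `normalization` (character),
#'   `seed` (integer), `out_dir` (path), `json_report` (path).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  known <- c("fit_window", "reference_temperature_c", "normalization",
             "seed", "out_dir", "json_report")
  cfg <- list(...)
  bad <- setdiff(names(cfg), known)
  if (length(bad) || (length(cfg) && any(!nzchar(names(cfg)))))
    sk_stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
            "sk_config_error")
  for (k in intersect(c("out_dir", "json_report"), names(cfg)))
    cfg[[k]] <- normalizePath(cfg[[k]], mustWork = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a machine-readable fit report
#'
#' Serialises the parameters, standard errors, point count and convergence
#' status of any fit object in the package to JSON.
#'
#' @param fit a fit object (`two_state_fit`, `ramp_ea`, `arrhenius_fit`,
#'   `sv_fit`, `si_fit`, ...).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- fit_report(fit)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit_report
#' @export
fit_report <- function(fit) UseMethod("fit_report")

#' @export
fit_report.default <- function(fit) {
  unclass(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
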