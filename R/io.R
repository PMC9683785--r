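# unit-bearing column headers: the file declares its own units; ambiguity
# is an error rather than a guess
.X_HEADERS <- c(T_K = "K", T_C = "C", urea_M = "M", GdmCl_M = "M",
                denat_M = "M")

.read_delim_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

.check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) {
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(v))
    if (length(bad)) {
      stop(sprintf("%s: column '%s', row %d: unparseable number '%s'",
                   path, col, bad[1] + 1L, v[bad[1]]))
    }
    v <- num
  }
  v
}

#' Read a delimited unfolding-curve table
#'
#' Expects a header row with a unit-declaring x column (`T_K`, `T_C`,
#' `urea_M`, `GdmCl_M` or `denat_M`) and a `signal` column. CSV or TSV is
#' chosen by extension. Malformed numbers are reported with file, row and
#' column.
#'
#' @param path file path
#' @param axis_kind override the axis kind inferred from the header
#'   (required for `denat_M`, where the denaturant identity is ambiguous)
#' @param technique detection technique metadata
#' @return an [unfolding_curve()]
#' @export
read_unfolding_table <- function(path, axis_kind = NULL,
                                 technique = "CD_far_UV") {
  df <- .read_delim_checked(path)
  xcol <- intersect(names(.X_HEADERS), names(df))
  if (length(xcol) != 1) {
    stop(path, ": need exactly one x column among ",
         paste(names(.X_HEADERS), collapse = ", "))
  }
  if (!"signal" %in% names(df)) stop(path, ": missing 'signal' column")
  x <- .check_numeric_col(df, xcol, path)
  y <- .check_numeric_col(df, "signal", path)
  inferred <- switch(xcol, T_K = "temperature", T_C = "temperature",
                     urea_M = "urea", GdmCl_M = "GdmCl", denat_M = NA)
  if (is.na(inferred) && is.null(axis_kind)) {
    stop(path, ": 'denat_M' header needs an explicit axis_kind")
  }
  unfolding_curve(x, y, axis_kind = if (is.null(axis_kind)) inferred
                                    else axis_kind,
                  technique = technique,
                  x_unit = if (xcol == "T_C") "C"
                           else if (xcol == "T_K") "K" else "M")
}

#' Write an unfolding curve as TSV
#'
#' Emits the same dialect [read_unfolding_table()] reads (Kelvin / molar
#' headers), so generated datasets round-trip.
#'
#' @param curve an [unfolding_curve()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_unfolding_table <- function(curve, path) {
  xcol <- switch(curve$axis_kind, temperature = "T_K", urea = "urea_M",
                 GdmCl = "GdmCl_M")
  df <- stats::setNames(data.frame(curve$x, curve$signal),
                        c(xcol, "signal"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DSC thermogram table
#'
#' Header must declare temperature units (`T_K` or `T_C`) and carry a
#' `Cp_kJ` column (molar heat capacity, kJ/(K mol)).
#'
#' @param path file path
#' @return a [thermogram()]
#' @export
read_thermogram_table <- function(path) {
  df <- .read_delim_checked(path)
  xcol <- intersect(c("T_K", "T_C"), names(df))
  if (length(xcol) != 1) stop(path, ": need exactly one of T_K, T_C")
  if (!"Cp_kJ" %in% names(df)) stop(path, ": missing 'Cp_kJ' column")
  thermogram(.check_numeric_col(df, xcol, path),
             .check_numeric_col(df, "Cp_kJ", path),
             x_unit = if (xcol == "T_C") "C" else "K")
}

#' @rdname read_thermogram_table
#' @param tg a [thermogram()]
#' @export
write_thermogram_table <- function(tg, path) {
  utils::write.table(data.frame(T_K = tg$T_K, Cp_kJ = tg$Cp), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CEST profile table
#'
#' Columns: `residue`, `nucleus`, `B0_MHz` (nucleus frequency), `nu1_Hz`,
#' `Tex_s`, `offset_ppm`, `intensity_ratio`. Returns profiles grouped by
#' residue, each residue holding one profile per B1 field — the structure
#' [fit_cest_global()] takes.
#'
#' @param path file path
#' @return named list (per residue) of lists of [cest_profile()]s
#' @export
read_cest_table <- function(path) {
  df <- .read_delim_checked(path)
  need <- c("residue", "nucleus", "B0_MHz", "nu1_Hz", "Tex_s",
            "offset_ppm", "intensity_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in setdiff(need, c("residue", "nucleus"))) {
    df[[col]] <- .check_numeric_col(df, col, path)
  }
  out <- lapply(split(df, df$residue), function(dr) {
    lapply(split(dr, dr$nu1_Hz), function(dp) {
      cest_profile(dp$residue[1], dp$offset_ppm, dp$intensity_ratio,
                   nu1_Hz = dp$nu1_Hz[1], freq_MHz = dp$B0_MHz[1],
                   Tex_s = dp$Tex_s[1],
                   nucleus = dp$nucleus[1])
    })
  })
  out[order(names(out))]
}

#' @rdname read_cest_table
#' @param residue_profiles structure returned by [gen_cest()] /
#'   [read_cest_table()]
#' @export
write_cest_table <- function(residue_profiles, path) {
  rows <- lapply(unlist(residue_profiles, recursive = FALSE),
                 function(p) {
    data.frame(residue = p$residue, nucleus = p$nucleus,
               B0_MHz = p$freq_MHz, nu1_Hz = p$nu1_Hz, Tex_s = p$Tex_s,
               offset_ppm = p$offsets_ppm,
               intensity_ratio = p$intensity_ratio)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single protein sequence from FASTA
#'
#' Validates that the record holds only the 20 standard one-letter residue
#' codes; lowercase input is uppercased.
#'
#' @param path FASTA path
#' @param index record to take when the file has several (error otherwise)
#' @return character scalar, the residue string
#' @export
read_fasta_sequence <- function(path, index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta_sequence needs the Biostrings package")
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop(path, ": no FASTA record found")
  if (length(set) > 1 && is.null(index)) {
    stop(path, ": multiple records; supply index")
  }
  i <- if (is.null(index)) 1L else index
  if (i > length(set)) stop(path, ": record index out of range")
  seqs <- toupper(as.character(set[[i]]))
  bad <- setdiff(strsplit(seqs, "")[[1]],
                 strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad)) {
    stop(path, ": illegal residue code(s): ", paste(bad, collapse = ", "))
  }
  seqs
}

#' Read a residue heat-capacity contribution table
#'
#' Rows: the 20 one-letter residue codes plus `backbone`, `Nterm`, `Cterm`;
#' columns: contributions (J/(K mol)) at 5, 25, 50, 75, 100 and 125 degC.
#' The packaged default, `unfolded_cp_synthetic.tsv`, is a synthetic
#' stand-in constructed with the qualitative shape of group-additivity
#' unfolded-state heat capacities (values rise with temperature and flatten
#' above ~75 degC); it supports the sequence-based route to the parabola
#' coefficient `c` but is not transcribed from a literature source — for
#' quantitative work supply your own table or fix `c` directly.
#'
#' @param path TSV path; defaults to the packaged synthetic table
#' @return matrix (rows = groups, cols = 6 temperatures), J/(K mol)
#' @export
read_residue_cp_table <- function(path = system.file(
    "extdata", "unfolded_cp_synthetic.tsv", package = "kowtherm")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$group
  if (!all(c("backbone", "Nterm", "Cterm") %in% rownames(m))) {
    stop("table must include backbone, Nterm and Cterm rows")
  }
  # the method presumes contributions that rise and then flatten with T
  d <- t(apply(m, 1, diff))
  if (any(d < -1e-9)) stop("contributions must be non-decreasing in T")
  m
}

#' Assemble a serializable result record
#'
#' Captures what a fit produced and how: analysis kind, parameters with
#' standard errors, diagnostics, the seed(s) involved, and the package
#' version. Re-running with identical inputs and seeds reproduces an
#' identical payload.
#'
#' @param kind analysis kind string (e.g. `"thermal_two_state"`)
#' @param parameters named numeric vector/list of fitted parameters
#' @param se named standard errors
#' @param diagnostics list of diagnostics (flags, residual norms, ...)
#' @param seed seed(s) used for any randomness (NA for deterministic runs)
#' @return list of class `result_record`
#' @export
result_record <- function(kind, parameters, se = NULL, diagnostics = NULL,
                          seed = NA) {
  structure(list(
    kind = kind,
    parameters = as.list(parameters),
    se = if (is.null(se)) NULL else as.list(se),
    diagnostics = diagnostics,
    seed = seed,
    package_version = as.character(utils::packageVersion("kowtherm"))),
    class = "result_record")
}

#' Write result records as JSON
#'
#' @param records a [result_record()] or list of them
#' @param path output path
#' @return `path`, invisibly
#' @export
write_result_json <- function(records, path) {
  if (inherits(records, "result_record")) records <- list(records)
  jsonlite::write_json(lapply(records, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
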