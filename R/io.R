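# CSV dialect shared by all instrument tables: comma-separated, '.'
# decimal, '#'-prefixed "key=value" metadata lines above a single header
# row, one table per file. Numbers are written with 12 significant digits,
# so write_table(read_table(x)) is byte-identical for files in this
# canonical form.

.schema_registry <- list(
  titration = list(
    columns = c("ligand_conc_m", "response"),
    meta = c("macromolecule_conc_m", "wavelength_nm", "kind", "path_cm")),
  melting = list(
    columns = c("temperature_c", "absorbance"),
    meta = c("label")),
  voltammogram = list(
    columns = c("potential_v", "current_a"),
    meta = character()),
  flow = list(
    columns = c("ligand_conc_m", "t_s"),
    meta = c("t0_s", "dna_conc_m")),
  rheogram = list(
    columns = c("shear_rate_per_s", "shear_stress_pa"),
    meta = c("label")),
  calibration = list(
    columns = c("conc_um", "current_a"),
    meta = character())
)

#' Read an instrument table from CSV
#'
#' Parses the package's canonical CSV dialect (see Details) and returns the
#' validated domain object for `schema`. Column names are matched
#' case-insensitively; metadata (fixed concentrations, units context) comes
#' from `# key=value` comment lines.
#'
#' @details Supported schemas and their columns / metadata keys:
#' * `"titration"`: `ligand_conc_m`, `response`; metadata
#'   `macromolecule_conc_m` (required), `wavelength_nm`, `kind`, `path_cm`.
#' * `"melting"`: `temperature_c`, `absorbance`; metadata `label`.
#' * `"voltammogram"`: `potential_v`, `current_a`; scan parameters as
#'   metadata.
#' * `"flow"`: `ligand_conc_m`, `t_s`; metadata `t0_s`, `dna_conc_m`
#'   (both required).
#' * `"rheogram"`: `shear_rate_per_s`, `shear_stress_pa`; metadata `label`.
#' * `"calibration"`: `conc_um`, `current_a` (plain data frame returned).
#'
#' @param path File path.
#' @param schema One of `"titration"`, `"melting"`, `"voltammogram"`,
#'   `"flow"`, `"rheogram"`, `"calibration"`.
#' @return The corresponding validated domain object; load problems raise
#'   errors of class `dnabind_load_error` naming the offending row/column.
#' @export
read_table <- function(path, schema = names(.schema_registry)) {
  schema <- match.arg(schema)
  if (!file.exists(path))
    .load_error(path, "file does not exist")
  spec <- .schema_registry[[schema]]
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(data_lines) < 2L)
    .load_error(path, "no data rows")
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- tolower(trimws(substr(kv, 1L, eq - 1L)))
      meta[[key]] <- trimws(substr(kv, eq + 1L, nchar(kv)))
    }
  }
  header <- tolower(trimws(strsplit(data_lines[1L], ",", fixed = TRUE)[[1L]]))
  missing_cols <- setdiff(spec$columns, header)
  if (length(missing_cols))
    .load_error(path, sprintf("missing column(s): %s",
                              paste(missing_cols, collapse = ", ")))
  rows <- strsplit(data_lines[-1L], ",", fixed = TRUE)
  cols <- lapply(seq_along(spec$columns), function(j) {
    jj <- match(spec$columns[j], header)
    vals <- vapply(rows, function(r) if (jj <= length(r))
      trimws(r[jj]) else NA_character_, character(1L))
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals))
    if (length(bad))
      .load_error(path, sprintf("non-numeric cell in column '%s', row %d",
                                spec$columns[j], bad[1L]))
    num
  })
  names(cols) <- spec$columns

  get_meta_num <- function(key, default = NULL, required = FALSE) {
    v <- meta[[key]]
    if (is.null(v)) {
      if (required)
        .load_error(path, sprintf("missing required metadata '%s'", key))
      return(default)
    }
    as.numeric(v)
  }

  obj <- tryCatch(
    switch(schema,
      titration = titration_series(
        cols$ligand_conc_m, cols$response,
        macromolecule_conc = get_meta_num("macromolecule_conc_m",
                                          required = TRUE),
        wavelength_nm = get_meta_num("wavelength_nm", 260),
        kind = meta[["kind"]] %||% "uv_absorbance",
        path_cm = get_meta_num("path_cm", 1)),
      melting = melting_curve(cols$temperature_c, cols$absorbance,
                              label = meta[["label"]] %||% "sample"),
      voltammogram = voltammogram(cols$potential_v, cols$current_a,
                                  metadata = meta),
      flow = flow_time_series(get_meta_num("t0_s", required = TRUE),
                              cols$t_s, cols$ligand_conc_m,
                              dna_conc = get_meta_num("dna_conc_m",
                                                      required = TRUE)),
      rheogram = rheogram(cols$shear_rate_per_s, cols$shear_stress_pa,
                          label = meta[["label"]] %||% "sample"),
      calibration = data.frame(conc_um = cols$conc_um,
                               current_a = cols$current_a)),
    error = function(e) .load_error(path, conditionMessage(e)))
  obj
}

.load_error <- function(path, msg) {
  stop(structure(
    class = c("dnabind_load_error", "error", "condition"),
    list(message = sprintf("%s: %s", path, msg), call = NULL)))
}

.fmt_num <- function(x) sprintf("%.12g", x)

#' Write a domain object to the canonical CSV dialect
#'
#' Inverse of [read_table()]. Metadata becomes `# key=value` lines, numbers
#' are printed with 12 significant digits, and the output is byte-stable:
#' writing the result of reading a canonical file reproduces it exactly.
#'
#' @param x A domain object ([titration_series()], [melting_curve()],
#'   [voltammogram()], [flow_time_series()], [rheogram()]) or a calibration
#'   data frame with columns `conc_um`, `current_a`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "titration_series")) {
    meta <- c(
      sprintf("# macromolecule_conc_m=%s",
              .fmt_num(attr(x, "macromolecule_conc"))),
      sprintf("# wavelength_nm=%s", .fmt_num(attr(x, "wavelength_nm"))),
      sprintf("# kind=%s", attr(x, "kind")),
      sprintf("# path_cm=%s", .fmt_num(attr(x, "path_cm"))))
    body <- c("ligand_conc_m,response",
              paste(.fmt_num(x$ligand_conc), .fmt_num(x$response),
                    sep = ","))
  } else if (inherits(x, "melting_curve")) {
    meta <- sprintf("# label=%s", attr(x, "label"))
    body <- c("temperature_c,absorbance",
              paste(.fmt_num(x$temperature), .fmt_num(x$absorbance),
                    sep = ","))
  } else if (inherits(x, "voltammogram")) {
    md <- attr(x, "metadata")
    keys <- names(md)[vapply(md, function(v)
      is.numeric(v) || is.character(v), logical(1L))]
    meta <- vapply(keys, function(k) {
      v <- md[[k]]
      sprintf("# %s=%s", k, if (is.numeric(v)) .fmt_num(v) else v)
    }, character(1L))
    body <- c("potential_v,current_a",
              paste(.fmt_num(x$potential), .fmt_num(x$current),
                    sep = ","))
  } else if (inherits(x, "flow_time_series")) {
    meta <- c(sprintf("# t0_s=%s", .fmt_num(attr(x, "t0"))),
              sprintf("# dna_conc_m=%s", .fmt_num(attr(x, "dna_conc"))))
    body <- c("ligand_conc_m,t_s",
              paste(.fmt_num(x$ligand_conc), .fmt_num(x$t), sep = ","))
  } else if (inherits(x, "rheogram")) {
    meta <- sprintf("# label=%s", attr(x, "label"))
    body <- c("shear_rate_per_s,shear_stress_pa",
              paste(.fmt_num(x$shear_rate), .fmt_num(x$shear_stress),
                    sep = ","))
  } else if (is.data.frame(x) && all(c("conc_um", "current_a") %in%
                                     names(x))) {
    meta <- character()
    body <- c("conc_um,current_a",
              paste(.fmt_num(x$conc_um), .fmt_num(x$current_a), sep = ","))
  } else {
    stop("write_table does not know this object type", call. = FALSE)
  }
  writeLines(c(meta, body), path)
  invisible(path)
}
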