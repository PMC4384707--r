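#' Read a time-activity curve TSV
#'
#' Expected header: `organ  time_h  activity_bq  decay_corrected`
#' (the last column optional, default FALSE).
#'
#' @param path File path.
#' @return A `tac` table.
#' @export
read_tac_tsv <- function(path) {
  as_tac(readr::read_tsv(path, show_col_types = FALSE))
}

#' Write a time-activity curve TSV
#' @param curves A `tac` table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tac_tsv <- function(curves, path) {
  readr::write_tsv(as_tac(curves), path)
  invisible(path)
}

#' Read a nuclide definition YAML
#'
#' Key-value file with `half_life_h` and a `lines` list of
#' `{yield, energy_mev}` entries.
#'
#' @param path File path.
#' @return An [alpha_spectrum()].
#' @export
read_nuclide_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$lines) || is.null(y$half_life_h)) {
    stop_atdose("read_nuclide_yaml(): need 'half_life_h' and 'lines' entries")
  }
  alpha_spectrum(
    yield = purrr::map_dbl(y$lines, "yield"),
    energy_mev = purrr::map_dbl(y$lines, "energy_mev"),
    half_life_h = y$half_life_h
  )
}

#' Read an organ geometry TSV
#'
#' Header: `organ  mass_kg  absorbed_fraction` (last column optional,
#' default 1).
#'
#' @param path File path.
#' @return Tibble `organ`, `mass_kg`, `absorbed_fraction`.
#' @export
read_organs_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("organ", "mass_kg") %in% names(x))) {
    stop_atdose("read_organs_tsv(): need columns organ, mass_kg")
  }
  if (!"absorbed_fraction" %in% names(x)) x$absorbed_fraction <- 1
  if (any(x$mass_kg <= 0)) stop_atdose("read_organs_tsv(): masses must be > 0")
  x
}

#' Read an expression matrix with sample metadata
#'
#' The matrix TSV has probe ids in the first column and one column per
#' sample array; the samples TSV has the metadata columns of
#' [expression_study()].
#'
#' @param matrix_path,samples_path File paths.
#' @param probe_genes_path Optional two-column TSV `probe  gene`.
#' @return An [expression_study()].
#' @export
read_expression_tsv <- function(matrix_path, samples_path, probe_genes_path = NULL) {
  m <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  mat <- as.matrix(m[, -1])
  rownames(mat) <- as.character(m[[1]])
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  pg <- if (!is.null(probe_genes_path)) {
    readr::read_tsv(probe_genes_path, show_col_types = FALSE)
  }
  expression_study(mat, samples, pg)
}

#' Write an expression study to TSVs
#' @param study An [expression_study()].
#' @param matrix_path,samples_path,probe_genes_path Output paths
#'   (`probe_genes_path` optional).
#' @return Invisibly, the paths written.
#' @export
write_expression_tsv <- function(study, matrix_path, samples_path,
                                 probe_genes_path = NULL) {
  readr::write_tsv(
    dplyr::bind_cols(tibble(probe = rownames(study$matrix)),
                     as_tibble(study$matrix)),
    matrix_path
  )
  readr::write_tsv(study$samples, samples_path)
  if (!is.null(probe_genes_path)) readr::write_tsv(study$probe_genes, probe_genes_path)
  invisible(c(matrix_path, samples_path, probe_genes_path))
}

#' Read a GO annotation table
#'
#' Either a simple two-column TSV (`gene  go_id`, header optional in that
#' order) or a GAF 2.x file, from which only the object identifier
#' (column 2) and GO id (column 5) are used; GAF comment lines start
#' with `!`.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return Tibble `gene`, `go_id`.
#' @export
read_annotation <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    lines <- readr::read_lines(path)
    lines <- lines[!startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- lengths(fields) >= 5
    tibble(
      gene = purrr::map_chr(fields[keep], 2),
      go_id = purrr::map_chr(fields[keep], 5)
    ) |> distinct()
  } else {
    x <- readr::read_tsv(path, show_col_types = FALSE)
    if (!all(c("gene", "go_id") %in% names(x))) {
      names(x)[1:2] <- c("gene", "go_id")
    }
    distinct(x[, c("gene", "go_id")])
  }
}

#' Read a GO category map TSV
#'
#' Header: `go_id  category  subcategory`.
#'
#' @param path File path.
#' @return Tibble `go_id`, `category`, `subcategory`.
#' @export
read_catmap_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("go_id", "category", "subcategory")
  if (!all(need %in% names(x))) {
    stop_atdose("read_catmap_tsv(): need columns %s", toString(need))
  }
  dup <- x |> dplyr::count(.data$go_id) |> filter(.data$n > 1)
  x[, need]
}

#' Bundled reference organ doses at 1.7 kBq
#'
#' Mean absorbed doses (mGy) per organ at 1 h, 6 h and 7 d after i.v.
#' administration of 1.7 kBq of the alpha emitter — the reference column of
#' the worked activity-scaling example.
#'
#' @return Tibble `organ`, `time_h`, `activity_kbq`, `dose_mgy`.
#' @export
reference_doses <- function() {
  readr::read_tsv(
    system.file("extdata", "at211_reference_doses.tsv", package = "atdose"),
    show_col_types = FALSE
  )
}
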