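#' Read a food web from canonical JSON
#'
#' The canonical schema is a JSON object with fields `name` (optional),
#' `species` (array of N unique labels), `flows` (N x N array of arrays,
#' row = source, column = target), and `imports`, `exports`, `respiration`
#' (arrays of length N).  All values are non-negative fluxes.
#'
#' @param path path to a JSON file.
#' @return A validated [foodweb()].
#' @seealso [write_foodweb_json()], [read_flow_matrix_tsv()],
#'   [read_s1_foodweb()]
#' @export
read_foodweb_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  foodweb_from_list(raw, source = path)
}

foodweb_from_list <- function(raw, source = "input") {
  required <- c("species", "flows", "imports", "exports", "respiration")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("%s: missing required field(s): %s.",
                  source, toString(missing)))
  }
  species <- as.character(raw$species)
  n <- length(species)
  flows <- raw$flows
  if (is.list(flows)) {
    len <- lengths(flows)
    if (length(unique(len)) != 1L) {
      abort(sprintf("%s: `flows` is ragged (row lengths %s).",
                    source, toString(unique(len))))
    }
    flows <- do.call(rbind, lapply(flows, as.numeric))
  }
  flows <- as.matrix(flows)
  if (!identical(dim(flows), c(n, n))) {
    abort(sprintf("%s: `flows` must be %d x %d, got %d x %d.",
                  source, n, n, nrow(flows), ncol(flows)))
  }
  foodweb(flows,
          imports = as.numeric(raw$imports),
          exports = as.numeric(raw$exports),
          respiration = as.numeric(raw$respiration),
          species = species,
          name = raw$name %||% "foodweb")
}

#' Write a food web to canonical JSON
#'
#' @param web a `foodweb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_foodweb_json <- function(web, path) {
  validate_foodweb(web)
  obj <- list(name = web$name, species = web$species,
              flows = web$flows, imports = web$imports,
              exports = web$exports, respiration = web$respiration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a food web from a flow-matrix TSV
#'
#' Tab-separated layout: a header row with the species labels followed by the
#' reserved columns `import`, `export`, `respiration`; one row per source
#' species, whose first cell repeats the species label (and must match the
#' header order), then the N flux values, then the three environment values.
#'
#' @param path path to a TSV file.
#' @return A validated [foodweb()].
#' @export
read_flow_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  reserved <- c("import", "export", "respiration")
  if (length(header) < 4L || !identical(utils::tail(header, 3), reserved)) {
    abort(sprintf("%s: header must end with columns %s.",
                  path, toString(reserved)))
  }
  species <- header[seq(2L, length(header) - 3L)]
  n <- length(species)
  body <- cells[-1]
  if (length(body) != n) {
    abort(sprintf("%s: expected %d species rows, found %d.",
                  path, n, length(body)))
  }
  row_labels <- vapply(body, `[[`, character(1), 1L)
  if (!identical(row_labels, species)) {
    bad <- which(row_labels != species)[1]
    abort(sprintf("%s: row %d is labelled '%s' but the header has '%s'.",
                  path, bad, row_labels[bad], species[bad]))
  }
  values <- matrix(NA_real_, n, n + 3L)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != n + 4L) {
      abort(sprintf("%s: row %d has %d cells, expected %d.",
                    path, i, length(row), n + 4L))
    }
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("%s: non-numeric cell '%s' at row %d, column %d.",
                    path, row[-1][j], i, j))
    }
    values[i, ] <- v
  }
  foodweb(values[, seq_len(n), drop = FALSE],
          imports = values[, n + 1L], exports = values[, n + 2L],
          respiration = values[, n + 3L], species = species,
          name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a food web to a flow-matrix TSV
#'
#' @param web a `foodweb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flow_matrix_tsv <- function(web, path) {
  validate_foodweb(web)
  m <- cbind(web$flows, web$imports, web$exports, web$respiration)
  df <- data.frame(species = web$species, m, check.names = FALSE)
  names(df) <- c("species", web$species, "import", "export", "respiration")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a supplementary-style food web JSON through a key mapping
#'
#' Adapter for supplementary data files whose JSON uses different key names
#' than the canonical schema.  `mapping` translates canonical keys
#' (`name`, `species`, `flows`, `imports`, `exports`, `respiration`) to the
#' keys used in the file; it may be a named list/character vector or the path
#' to a YAML file of the same shape.  Keys absent from the mapping are looked
#' up under their canonical name.  Unknown structure fails loudly, listing the
#' keys actually present in the file.
#'
#' @param path path to the JSON file.
#' @param mapping named list/character vector or YAML file path; `NULL` means
#'   the file already uses canonical keys.
#' @return A validated [foodweb()].
#' @export
read_s1_foodweb <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- yaml::read_yaml(mapping)
  }
  mapping <- as.list(mapping %||% list())
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  canonical <- c("name", "species", "flows", "imports", "exports",
                 "respiration")
  out <- list()
  for (key in canonical) {
    src <- mapping[[key]] %||% key
    if (!is.null(raw[[src]])) out[[key]] <- raw[[src]]
  }
  missing <- setdiff(setdiff(canonical, "name"), names(out))
  if (length(missing)) {
    abort(sprintf(
      "%s: cannot locate field(s) %s; file has keys: %s. Supply a `mapping`.",
      path, toString(missing), toString(names(raw))
    ))
  }
  foodweb_from_list(out, source = path)
}
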