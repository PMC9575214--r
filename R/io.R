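#' Write a connectivity matrix as tab-delimited text
#'
#' Square TSV with region labels as header row and first column.
#'
#' @param m Symmetric `V x V` matrix.
#' @param path Output file.
#' @param labels Optional region labels (default from the matrix or
#'   `R01..RV`).
#' @export
write_connectivity_matrix <- function(m, path, labels = NULL) {
  m <- as.matrix(m)
  V <- nrow(m)
  if (is.null(labels)) {
    labels <- rownames(m)
    if (is.null(labels)) labels <- sprintf("R%02d", seq_len(V))
  }
  dimnames(m) <- list(labels, labels)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read a connectivity (or time-series) matrix from delimited text
#'
#' Accepts TSV or CSV, with or without a header row / label column; the
#' layout is sniffed from the first line.
#'
#' @param path Input file.
#' @return Numeric matrix (with dimnames when labels are present).
#' @export
read_connectivity_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tokens <- strsplit(first, sep, fixed = TRUE)[[1L]]
  numeric_first <- !is.na(suppressWarnings(as.numeric(tokens[tokens != ""])))
  has_header <- !all(numeric_first)
  if (has_header) {
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, row.names = 1L)
  } else {
    df <- utils::read.table(path, sep = sep, header = FALSE)
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("malformed matrix file (non-numeric entries): ", path,
         call. = FALSE)
  }
  m
}

#' Write the subject manifest of a dataset
#'
#' CSV with columns `subject_id`, `group`, `path` (paths relative to the
#' manifest's directory) and an optional `kind` column
#' (`"matrix"` or `"timeseries"`).
#'
#' @param manifest Data frame with those columns.
#' @param path Output CSV.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a two-group connectivity dataset from a manifest
#'
#' Reads every listed file (connectivity matrix, or region-by-time series
#' when `kind == "timeseries"`, converted via [ts_to_connectivity()]),
#' checks that all subjects share the same region count, vectorizes, and
#' assembles a [connectivity_dataset()].
#'
#' @param path Manifest CSV with columns `subject_id`, `group`, `path`.
#' @return A [connectivity_dataset()].
#' @export
load_dataset_from_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(man$kind)) man$kind <- "matrix"
  base <- dirname(normalizePath(path))
  mats <- vector("list", nrow(man))
  for (s in seq_len(nrow(man))) {
    f <- man$path[s]
    if (!file.exists(f)) f <- file.path(base, man$path[s])
    m <- read_connectivity_matrix(f)
    if (identical(man$kind[s], "timeseries")) m <- ts_to_connectivity(m)
    if (nrow(m) != ncol(m)) {
      stop("subject ", man$subject_id[s], ": matrix in ", man$path[s],
           " is not square", call. = FALSE)
    }
    mats[[s]] <- m
  }
  Vs <- vapply(mats, nrow, integer(1))
  if (length(unique(Vs)) != 1L) {
    stop("inconsistent region counts across subjects: ",
         paste(unique(Vs), collapse = ", "), call. = FALSE)
  }
  labels <- rownames(mats[[1L]])
  map <- edge_index_map(Vs[1L], labels)
  Y <- t(vapply(mats, vectorize_connectivity, numeric(map$E), map = map))
  connectivity_dataset(Y, man$group, map, man$subject_id)
}

#' Write a simulated dataset as matrix files plus manifest
#'
#' One TSV connectivity matrix per subject and a `manifest.csv` binding
#' subject ids, group labels and file paths.
#'
#' @param dataset A [connectivity_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "connectivity_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(dataset$Y))
  for (s in seq_len(nrow(dataset$Y))) {
    m <- devectorize_connectivity(dataset$Y[s, ], dataset$map)
    paths[s] <- sprintf("%s.tsv", dataset$subject_ids[s])
    write_connectivity_matrix(m, file.path(dir, paths[s]),
                              dataset$map$labels)
  }
  man <- data.frame(subject_id = dataset$subject_ids,
                    group = as.character(dataset$groups),
                    path = paths)
  write_manifest(man, file.path(dir, "manifest.csv"))
  file.path(dir, "manifest.csv")
}

#' Read a scenario file (YAML or JSON) into a scenario_config
#'
#' Unknown fields are rejected; missing fields take the
#' [scenario_config()] defaults. An `mcmc` block maps onto
#' [dp_hyperparameters()].
#'
#' @param path Scenario file.
#' @return A [scenario_config()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("V", "rho_within", "rho_between", "delta", "N",
               "effect_size", "effect_fraction", "psi_structure",
               "n_reps", "B", "alpha", "sigma_method", "mcmc", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown scenario fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$mcmc)) {
    raw$mcmc <- do.call(dp_hyperparameters, raw$mcmc)
  }
  tryCatch(do.call(scenario_config, raw), error = function(e) {
    stop("invalid scenario values: ", conditionMessage(e), call. = FALSE)
  })
}

#' Serialize a scenario_config to a plain list
#'
#' @param config A [scenario_config()].
#' @return A list suitable for YAML/JSON output.
#' @export
scenario_as_list <- function(config) {
  out <- unclass(config)
  out$mcmc <- unclass(out$mcmc)
  out$mcmc$seed <- NULL
  out$n_clusters <- NULL
  out
}
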