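#' Read and write beta matrices, sample sheets and results
#'
#' Beta matrices travel as TSV with sites as rows and a header row of
#' sample ids (the EWAS convention); sample sheets and results as CSV.
#' Files ending in `.gz` are read/written through a gzip connection.
#' Reading validates the value range and id uniqueness; writing then
#' reading reproduces values to full precision.
#'
#' @param path file path.
#' @return `read_beta`: numeric matrix (sites x samples).
#' @export
read_beta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, row.names = NULL)
  site_ids <- as.character(df[[1]])
  if (anyDuplicated(site_ids))
    stop("duplicate site ids in ", path, ": ",
         paste(head(unique(site_ids[duplicated(site_ids)]), 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in ", path)
  rownames(m) <- site_ids
  storage.mode(m) <- "double"
  bad <- which(is.na(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta values outside [0,1] (or missing), e.g. site %s sample %s = %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 format(m[bad[1, , drop = FALSE]])))
  m
}

#' @rdname read_beta
#' @param beta beta matrix to write.
#' @export
write_beta <- function(beta, path) {
  assert_beta_matrix(beta)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  df <- data.frame(site_id = rownames(beta), beta, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_beta
#' @export
read_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  assert_sheet(sheet)
  bad <- unlist(lapply(split(sheet, sheet$individual_id), function(d) {
    if (nrow(unique(d[, c("age", "sex", "brain_bank", "phenotype")])) > 1)
      d$individual_id[1] else NULL
  }))
  if (length(bad))
    stop("covariates/phenotype differ across samples of individual(s): ",
         paste(bad, collapse = ", "))
  sheet
}

#' @rdname read_beta
#' @param sheet sample sheet to write.
#' @export
write_sheet <- function(sheet, path) {
  assert_sheet(sheet)
  write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_beta
#' @param x an `ewas_fit`, `qc_report`, `two_stage_report` or data.frame.
#' @export
write_results <- function(x, path) {
  df <- if (is.data.frame(x)) x else as.data.frame(x)
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_defaults <- function(type) {
  switch(type,
    cohort = {
      cc <- cohort_config()
      cc[setdiff(names(cc), NULL)]
    },
    benchmark = unclass(sim_config()),
    power = list(alpha = 9e-8, delta = 0.05, n_per_group = 100L,
                 power_target = 0.8, coverage_target = 0.8, n_bins = 500L),
    stop("unknown config type: ", type))
}

#' Load a YAML configuration with defaults and typo protection
#'
#' Reads a YAML file and merges it over the documented defaults of the
#' requested configuration type. Unknown keys are rejected (no silent typo
#' acceptance) with a nearest-key suggestion. An empty or absent-key file
#' yields all defaults; the power defaults include the experiment-wide
#' significance threshold alpha = 9e-8.
#'
#' @param path YAML file path.
#' @param type one of "cohort", "benchmark", "power".
#' @return named list of resolved settings.
#' @export
load_config <- function(path, type = c("cohort", "benchmark", "power")) {
  type <- match.arg(type)
  defaults <- config_defaults(type)
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("no such file: ", path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    key <- unknown[1]
    d <- utils::adist(key, names(defaults))
    hint <- if (min(d) <= 3)
      paste0("; did you mean '", names(defaults)[which.min(d)], "'?") else ""
    stop("unknown configuration key '", key, "'", hint)
  }
  out <- utils::modifyList(defaults, user)
  if (type == "cohort" && is.list(out$sd_moments))
    out$sd_moments <- lapply(out$sd_moments, as.numeric)
  out
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: package
#' version, the fully resolved configuration, the master seed, input file
#' MD5 digests and a timestamp. Written as YAML next to the outputs of
#' every CLI run.
#'
#' @param path output path for the manifest.
#' @param config resolved configuration (named list).
#' @param seed master seed used.
#' @param inputs character vector of input file paths to digest.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA_integer_,
                           inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    tool = "sortedmeth",
    version = as.character(utils::packageVersion("sortedmeth")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_digests = digests,
    config = rapply(config, function(x)
      if (is.function(x)) NULL else x, how = "replace"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
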