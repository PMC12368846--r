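# internal helpers shared across modules

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-simulation seed stream derived from a master seed;
# values kept below .Machine$integer.max
derive_seeds <- function(master_seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

colVars_fast <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1L)
}

stop_config <- function(...) {
  stop(structure(class = c("sortedmeth_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("`beta` must be a numeric matrix (sites x samples)")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("`beta` must carry site ids as rownames and sample ids as colnames")
  invisible(TRUE)
}

assert_sheet <- function(sheet, need_phenotype = FALSE) {
  required <- c("sample_id", "individual_id", "cell_type", "age", "sex",
                "brain_bank", "phenotype")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  key <- paste(sheet$individual_id, sheet$cell_type)
  if (anyDuplicated(key))
    stop("duplicated (individual_id, cell_type) pairs in sample sheet: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (need_phenotype && !all(sheet$phenotype %in% c("case", "control")))
    stop("phenotype must be assigned (case/control) before this step; ",
         "see assign_phenotype()")
  invisible(TRUE)
}

align_beta_sheet <- function(beta, sheet) {
  assert_beta_matrix(beta)
  if (!setequal(colnames(beta), sheet$sample_id)) {
    off <- c(setdiff(colnames(beta), sheet$sample_id),
             setdiff(sheet$sample_id, colnames(beta)))
    stop("beta matrix and sample sheet refer to different samples: ",
         paste(head(off, 10), collapse = ", "))
  }
  sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
}
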