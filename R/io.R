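#' Read and write population recordings as long-format CSV
#'
#' The on-disk schema is one row per (neuron, stimulus, trial) cell:
#' columns `neuron_id` (string), `unit_kind` (`single`/`multi`), `state`
#' (adaptor um), `amplitude_um` (number), `trial` (integer >= 1), `count`
#' (integer >= 0), comma-separated with a header, UTF-8, dot decimal.
#' Trial indices are 1-based in files. The grid must be complete: every
#' neuron x amplitude x trial combination present exactly once. Reading is
#' strict -- missing columns, non-integer counts, duplicate cells and
#' incomplete grids are rejected with diagnostics naming the offending
#' cells.
#'
#' @param recording A [population_recording].
#' @param path File path.
#' @return `read_recording` returns a [population_recording];
#'   `write_recording` invisibly returns `path`.
#' @export
write_recording <- function(recording, path) {
  d <- dim(recording$counts)
  df <- data.frame(
    neuron_id = rep(recording$neuron_ids, times = d[2] * d[3]),
    unit_kind = rep(recording$unit_kind, times = d[2] * d[3]),
    state = recording$state,
    amplitude_um = rep(rep(recording$amplitudes, each = d[1]), times = d[3]),
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    count = as.vector(recording$counts))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "unit_kind", "state", "amplitude_um", "trial", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$count)) || any(df$count != round(df$count)) ||
      any(df$count < 0)) {
    bad <- which(df$count != round(df$count) | df$count < 0 |
                   !is.finite(df$count))
    stop(sprintf("non-integer or negative counts at rows: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (length(unique(df$state)) != 1)
    stop("a recording file must contain exactly one adaptation state",
         call. = FALSE)
  ids <- unique(df$neuron_id)
  amps <- sort(unique(df$amplitude_um))
  trials <- sort(unique(df$trial))
  if (!identical(trials, seq_along(trials)))
    stop("trial indices must be 1..T", call. = FALSE)
  key <- paste(df$neuron_id, df$amplitude_um, df$trial)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate cells (neuron, amplitude, trial): ",
         paste(utils::head(key[dup], 5), collapse = "; "), call. = FALSE)
  expected <- length(ids) * length(amps) * length(trials)
  if (nrow(df) != expected) {
    full <- paste(rep(ids, times = length(amps) * length(trials)),
                  rep(rep(amps, each = length(ids)), times = length(trials)),
                  rep(trials, each = length(ids) * length(amps)))
    missing_cells <- setdiff(full, key)
    stop("incomplete grid; missing cells (neuron amplitude trial): ",
         paste(utils::head(missing_cells, 5), collapse = "; "),
         call. = FALSE)
  }
  counts <- array(0L, dim = c(length(ids), length(amps), length(trials)))
  ni <- match(df$neuron_id, ids)
  ai <- match(df$amplitude_um, amps)
  counts[cbind(ni, ai, df$trial)] <- as.integer(df$count)
  kind <- df$unit_kind[match(ids, df$neuron_id)]
  population_recording(counts, amps, state = df$state[1],
                       unit_kind = kind, neuron_ids = ids)
}

#' Write a pairwise discriminability matrix as labeled CSV
#'
#' Writes an S x S matrix with amplitude row/column labels. With `lower`
#' given, the upper triangle holds `pair_A` and the lower triangle holds
#' the second matrix, mirroring the two-scheme matrix figures.
#'
#' @param pair_A S x S matrix (e.g. from [discriminability]).
#' @param path File path.
#' @param lower Optional second S x S matrix for the lower triangle.
#' @return Invisibly, `path`.
#' @export
write_pair_matrix <- function(pair_A, path, lower = NULL) {
  m <- pair_A
  if (!is.null(lower)) {
    if (!all(dim(lower) == dim(m)))
      stop("`lower` must match the dimensions of `pair_A`", call. = FALSE)
    m[lower.tri(m)] <- lower[lower.tri(lower)]
  }
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Read and write weight vectors as delimited text with JSON metadata
#'
#' The file holds one comment line `# {json metadata}` (scheme, trained
#' state, trial split) followed by CSV columns `neuron_id, weight`.
#'
#' @param w A [weight_vector].
#' @param path File path.
#' @param neuron_ids Optional identifiers (default `n01`, `n02`, ...).
#' @return `read_weights` returns a [weight_vector]; `write_weights`
#'   invisibly returns `path`.
#' @export
write_weights <- function(w, path, neuron_ids = NULL) {
  stopifnot(inherits(w, "weight_vector"))
  meta <- jsonlite::toJSON(
    list(scheme = w$scheme, trained_state = w$trained_state,
         trained_trial_ids = w$trained_trial_ids,
         degenerate = w$degenerate),
    auto_unbox = TRUE, null = "null", digits = NA)
  ids <- neuron_ids %||% sprintf("n%02d", seq_along(w$weights))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  writeLines("neuron_id,weight", con)
  writeLines(sprintf("%s,%.17g", ids, w$weights), con)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3 || !startsWith(lines[1], "# "))
    stop("not a weight-vector file (missing metadata header)", call. = FALSE)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  df <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE)
  weight_vector(df$weight, scheme = meta$scheme,
                trained_state = meta$trained_state %||% NA_real_,
                trained_trial_ids = meta$trained_trial_ids,
                degenerate = isTRUE(meta$degenerate))
}

#' Write an analysis report as JSON
#'
#' Serializes a [run_state_analysis] report (or any list of tables and
#' scalars) to pretty-printed JSON.
#'
#' @param report A `state_report`, `cross_state_result`, or plain list.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns",
                       na = "null")
  invisible(path)
}
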