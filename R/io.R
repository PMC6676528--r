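# Readers and writers for the minimal SynMap-like dialect (gene_id_1,
# gene_id_2, similarity TSV) and for the package's own report tables.
# Every output embeds its effective configuration as `# key: value` header
# lines so a run can be reproduced from its artefacts.

#' Read a gene-pair similarity table
#'
#' Reads a tab-separated table of gene pairs: two gene identifiers and
#' a similarity per row, with an optional fourth ground-truth column
#' (origin event) as written by [write_pair_table()].  A header row is
#' auto-detected (non-numeric third field).  Similarities greater than
#' 1 are interpreted as percentages and divided by 100.  Malformed rows
#' (wrong field count, non-numeric or out-of-range similarity) are
#' dropped and counted; more than `max_malformed` of them is an error.
#' Duplicate unordered pairs are removed with a warning.
#'
#' @param path Path to the TSV file (lines starting `#` are ignored).
#' @param max_malformed Tolerated fraction of malformed rows (default
#'   0.1).
#' @return A tibble of class `wgd_pair_table` with columns `gene_id_1`,
#'   `gene_id_2`, `similarity` (and `origin_event` when present);
#'   attributes `n_malformed` and `n_duplicates` record what was
#'   dropped.
#' @export
read_pair_table <- function(path, max_malformed = 0.1) {
  if (!file.exists(path)) stop_wgdfrac(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_wgdfrac(sprintf("empty pair table: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  third_num <- function(f) length(f) >= 3 && !is.na(suppressWarnings(as.numeric(f[3])))
  if (!third_num(fields[[1]])) {
    fields <- fields[-1]                      # header row
    if (!length(fields)) stop_wgdfrac(sprintf("pair table has a header but no rows: %s", path))
  }
  ok <- vapply(fields, third_num, logical(1))
  sim <- rep(NA_real_, length(fields))
  sim[ok] <- vapply(fields[ok], function(f) suppressWarnings(as.numeric(f[3])), numeric(1))
  sim_scaled <- ifelse(!is.na(sim) & sim > 1, sim / 100, sim)
  ok <- ok & !is.na(sim_scaled) & sim_scaled >= 0 & sim_scaled <= 1
  n_bad <- sum(!ok)
  if (n_bad / length(fields) > max_malformed)
    stop_wgdfrac(sprintf("%d of %d rows are malformed (> %.0f%% tolerated)",
                         n_bad, length(fields), 100 * max_malformed))
  if (n_bad > 0)
    warning(sprintf("dropped %d malformed row(s) from %s", n_bad, path), call. = FALSE)
  fields <- fields[ok]
  tbl <- tibble::tibble(
    gene_id_1 = vapply(fields, `[[`, character(1), 1),
    gene_id_2 = vapply(fields, `[[`, character(1), 2),
    similarity = sim_scaled[ok]
  )
  has4 <- all(vapply(fields, length, integer(1)) >= 4)
  if (has4) {
    o <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4)))
    if (!anyNA(o)) tbl$origin_event <- o
  }
  key <- paste(pmin(tbl$gene_id_1, tbl$gene_id_2),
               pmax(tbl$gene_id_1, tbl$gene_id_2), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("removed %d duplicate unordered pair(s)", sum(dup)), call. = FALSE)
    tbl <- tbl[!dup, ]
  }
  structure(tbl, class = c("wgd_pair_table", class(tbl)),
            n_malformed = n_bad, n_duplicates = sum(dup))
}

#' Write a gene-pair similarity table
#'
#' @param x A data frame with `gene_id_1`, `gene_id_2`, `similarity`
#'   (optionally `origin_event`, written as a fourth column and ignored
#'   by inference on re-read).
#' @param path Output path.
#' @param header Named character vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(x, path, header = character()) {
  need <- c("gene_id_1", "gene_id_2", "similarity")
  if (!all(need %in% names(x)))
    stop_wgdfrac("pair tables need columns gene_id_1, gene_id_2, similarity")
  cols <- c(need, intersect("origin_event", names(x)))
  write_tsv_with_header(x[, cols], path, header)
  invisible(path)
}

# shared writer: commented header block, then a TSV with column names
write_tsv_with_header <- function(tbl, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# read back any table written by write_tsv_with_header; header lines are
# returned as a named character vector attribute
read_tsv_with_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_lines <- lines[startsWith(lines, "# ")]
  hdr <- stats::setNames(
    sub("^# [^:]+: ", "", hdr_lines),
    sub("^# ([^:]+):.*$", "\\1", hdr_lines)
  )
  tbl <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  structure(tibble::as_tibble(tbl), header = hdr)
}

#' Write / read a fitted component table
#'
#' The component table (one row per mixture component: mean, sd,
#' weight, count) is the hand-off between mixture fitting and survival
#' inference.
#'
#' @param fit A `wgd_mixture_fit` (or a component tibble with those
#'   columns).
#' @param path File path.
#' @param header Named character vector of `# key: value` lines.
#' @return `path` (write) or a component tibble (read).
#' @export
write_component_table <- function(fit, path, header = character()) {
  tbl <- if (inherits(fit, "wgd_mixture_fit")) {
    header <- c(header,
                loglik = format(fit$loglik), n = format(fit$n),
                iterations = format(fit$iterations),
                converged = format(fit$converged))
    fit$components
  } else tibble::as_tibble(fit)
  need <- c("mean", "sd", "weight", "count")
  if (!all(need %in% names(tbl)))
    stop_wgdfrac("component tables need columns mean, sd, weight, count")
  write_tsv_with_header(tbl[, need], path, header)
  invisible(path)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  tbl <- read_tsv_with_header(path)
  need <- c("mean", "sd", "weight", "count")
  if (!all(need %in% names(tbl)))
    stop_wgdfrac("component tables need columns mean, sd, weight, count")
  tbl
}

#' Write a rates table
#'
#' @param rates A `wgd_rate_estimates` tibble from [rate_estimates()].
#' @param path Output path.
#' @param header Named character vector of `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_rates_table <- function(rates, path, header = character()) {
  if (!inherits(rates, "wgd_rate_estimates"))
    stop_wgdfrac("`rates` must come from rate_estimates()")
  write_tsv_with_header(tibble::as_tibble(rates), path, header)
  invisible(path)
}
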