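#' Read a coding sequence from a FASTA file
#'
#' @param path Path to a single- or multi-record FASTA file (DNA or RNA
#'   alphabet).
#' @param id Record id to select; defaults to the first record.
#' @return The coding sequence as a single uppercase string.
#' @export
read_cds_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  if (is.null(id)) {
    i <- 1L
  } else {
    i <- match(id, nm)
    if (is.na(i)) {
      stop(sprintf("record '%s' not found in %s (available: %s)", id, path,
                   paste(utils::head(nm, 10), collapse = ", ")), call. = FALSE)
    }
  }
  toupper(as.character(seqs[[i]]))
}

#' Read a codon rate table from TSV
#'
#' The file has two columns, `codon` and `value`, and declares the value
#' kind either in a comment line `# value_kind: time_s` (or `rate_aa_per_s`)
#' or through a `value_kind` column.
#'
#' @param path Path to the TSV file.
#' @return A [codon_rate_table()].
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("rate table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kind_line <- grep("^#\\s*value_kind\\s*:", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  if (!all(c("codon", "value") %in% names(df))) {
    stop(sprintf("%s: expected columns 'codon' and 'value', found: %s",
                 path, paste(names(df), collapse = ", ")), call. = FALSE)
  }
  kind_raw <- if (length(kind_line) > 0L) {
    trimws(sub("^#\\s*value_kind\\s*:", "", kind_line[1]))
  } else if ("value_kind" %in% names(df)) {
    df$value_kind[1]
  } else {
    stop(sprintf("%s: no value_kind declaration (comment '# value_kind: time_s' or column)",
                 path), call. = FALSE)
  }
  kind <- switch(kind_raw,
                 time_s = "time", time = "time",
                 rate_aa_per_s = "rate", rate = "rate",
                 stop(sprintf("%s: unknown value_kind '%s'", path, kind_raw),
                      call. = FALSE))
  bad <- which(!is.finite(df$value) | df$value <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-positive or missing value at data line %d (codon %s)",
                 path, bad[1], df$codon[bad[1]]), call. = FALSE)
  }
  codon_rate_table(stats::setNames(df$value, df$codon), kind = kind,
                   label = basename(path))
}

#' Write a codon rate table to TSV
#'
#' @param table A [codon_rate_table()].
#' @param path Output path.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "codon_rate_table"))
  kind <- if (identical(table$kind, "time")) "time_s" else "rate_aa_per_s"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# value_kind: %s", kind), con)
  utils::write.table(data.frame(codon = names(table$values),
                                value = unname(table$values)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a construct / protocol configuration file
#'
#' A flat YAML key-value file with the keys `name`, `total_codons`,
#' `domain_start`, `domain_end`, `tunnel_length`, `observable_last` (or
#' `observable_codons`), `bulk_kF`, `bulk_kU` for the construct, and
#' optionally `pulse_s`, `chase_s`, `delay_s`, `dt_s` for the protocol.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `construct` and `protocol` (the latter
#'   `NULL` when no protocol keys are present).
#' @export
read_construct_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("total_codons", "domain_start", "domain_end", "bulk_kF", "bulk_kU")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing required key(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  obs <- if (!is.null(cfg$observable_codons)) {
    as.integer(cfg$observable_codons)
  } else if (!is.null(cfg$observable_last)) {
    seq_len(as.integer(cfg$observable_last))
  } else {
    seq.int(cfg$domain_start, cfg$domain_end)
  }
  cst <- construct(name = cfg$name %||% basename(path),
                   M = cfg$total_codons,
                   domain_start = cfg$domain_start,
                   domain_end = cfg$domain_end,
                   bulk_kF = cfg$bulk_kF, bulk_kU = cfg$bulk_kU,
                   tunnel_length = cfg$tunnel_length %||% 30,
                   observable_codons = obs)
  proto <- NULL
  if (any(c("pulse_s", "chase_s", "delay_s", "dt_s") %in% names(cfg))) {
    chase <- cfg$chase_s %||% 360
    proto <- pulse_protocol(pulse = cfg$pulse_s %||% 45, chase = chase,
                            delay = cfg$delay_s %||% 10,
                            dt = cfg$dt_s %||% 0.1,
                            report_times = seq(0, chase, by = 1))
  }
  list(construct = cst, protocol = proto)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a folding curve or profile as CSV
#'
#' Curves are written with columns `time_s`, `P_F` (and `sem` for
#' stochastic results); profiles with columns `codon`, `P_F_B`.
#'
#' @param x A `folding_curve`, `simulation_result` or
#'   `steady_state_profile`.
#' @param path Output path.
#' @export
write_curve_csv <- function(x, path) {
  df <- if (inherits(x, "folding_curve")) {
    as.data.frame(x)
  } else if (inherits(x, "simulation_result")) {
    data.frame(time_s = x$time, P_F = x$mean, sem = x$sem)
  } else if (inherits(x, "steady_state_profile")) {
    data.frame(codon = seq_len(x$M), P_F_B = x$values)
  } else {
    stop("unsupported object for write_curve_csv", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a run-metadata block
#'
#' Every CLI run attaches this metadata (inputs, parameters, seed, package
#' version) to its JSON summary so results are reproducible.
#'
#' @param inputs Named list of input paths/identifiers.
#' @param parameters Named list of run parameters.
#' @param seed Integer seed or `NULL`.
#' @return A list suitable for JSON serialization.
#' @export
run_metadata <- function(inputs = list(), parameters = list(), seed = NULL) {
  list(package = "cotfold",
       version = as.character(utils::packageVersion("cotfold")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, inputs = inputs, parameters = parameters)
}
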