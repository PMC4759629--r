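#' Nascent-chain length at which a domain can first fold
#'
#' A domain is sterically unable to fold until it has fully emerged from
#' the ribosome exit tunnel, i.e. until the nascent chain is
#' `domain_end + tunnel_length` residues long. Folding is permitted at this
#' length and beyond; the position-resolved folding and unfolding rates are
#' zero strictly below it.
#'
#' @param domain_end Last codon (1-based, inclusive) of the folding domain.
#' @param tunnel_length Number of residues occluded by the exit tunnel
#'   (default 30, consistent with the 24-40 residue linker lengths reported
#'   for domain folding near the tunnel).
#' @return The onset codon index.
#' @export
folding_onset <- function(domain_end, tunnel_length = 30) {
  if (!is.numeric(domain_end) || domain_end < 1) {
    stop("`domain_end` must be a codon index >= 1", call. = FALSE)
  }
  if (!is.numeric(tunnel_length) || tunnel_length < 0) {
    stop("`tunnel_length` must be >= 0", call. = FALSE)
  }
  as.integer(domain_end + tunnel_length)
}

#' Protein construct: geometry, labelling and folding parameters
#'
#' Bundles everything the kinetic model needs to know about one protein
#' construct: its length in codons (including the stop codon), the codon
#' interval encoding the co-translationally folding domain, the exit-tunnel
#' linker length, the set of codon positions whose residues carry a
#' detectable label (e.g. Met/Cys positions in a radiolabelling
#' experiment), and the domain's bulk folding and unfolding rates.
#'
#' @param name Construct name.
#' @param M Total number of codons including the stop codon.
#' @param domain_start,domain_end Codon interval (1-based, inclusive) of
#'   the folding domain; `domain_end` must be < `M`.
#' @param bulk_kF,bulk_kU Bulk folding and unfolding rates, per second;
#'   non-negative and not both zero.
#' @param tunnel_length Exit-tunnel linker length in residues (default 30).
#' @param observable_codons Codon indices whose residues are detectable by
#'   the assay; defaults to the full domain interval. Must lie in
#'   `[1, M-1]`.
#' @param observable_length Optional metadata: the assay's nominal
#'   observable length (defaults to `length(observable_codons)`).
#' @return An object of class `construct`.
#' @export
construct <- function(name, M, domain_start, domain_end, bulk_kF, bulk_kU,
                      tunnel_length = 30,
                      observable_codons = seq.int(domain_start, domain_end),
                      observable_length = length(observable_codons)) {
  M <- as.integer(M)
  domain_start <- as.integer(domain_start)
  domain_end <- as.integer(domain_end)
  if (!(1L <= domain_start && domain_start <= domain_end && domain_end < M)) {
    stop("require 1 <= domain_start <= domain_end < M", call. = FALSE)
  }
  if (bulk_kF < 0 || bulk_kU < 0 || (bulk_kF == 0 && bulk_kU == 0)) {
    stop("bulk rates must be >= 0 and not both zero", call. = FALSE)
  }
  observable_codons <- sort(unique(as.integer(observable_codons)))
  if (length(observable_codons) > 0L &&
      (min(observable_codons) < 1L || max(observable_codons) > M - 1L)) {
    stop("observable codons must lie within [1, M-1]", call. = FALSE)
  }
  onset <- folding_onset(domain_end, tunnel_length)
  if (onset >= M) {
    stop(sprintf(paste0("configuration error: folding onset %d >= M = %d; ",
                        "the domain can never fold on the ribosome"),
                 onset, M), call. = FALSE)
  }
  structure(list(name = name, M = M,
                 domain_start = domain_start, domain_end = domain_end,
                 tunnel_length = tunnel_length, onset = onset,
                 observable_codons = observable_codons,
                 observable_length = observable_length,
                 bulk_kF = bulk_kF, bulk_kU = bulk_kU),
            class = "construct")
}

#' @export
print.construct <- function(x, ...) {
  cat(sprintf("<construct> %s: M = %d, domain %d-%d, onset %d (tunnel %g aa)\n",
              x$name, x$M, x$domain_start, x$domain_end, x$onset,
              x$tunnel_length))
  cat(sprintf("  bulk kF = %g /s, kU = %g /s; %d observable codons\n",
              x$bulk_kF, x$bulk_kU, length(x$observable_codons)))
  invisible(x)
}

#' Position-resolved folding kinetics of a construct
#'
#' Expands a construct into per-position folding and unfolding rates: zero
#' for nascent-chain lengths below the folding onset and the bulk rates at
#' the onset and beyond (the two-regime form of the model). The
#' equilibrium folded probability `P_eq,i = kF_i / (kF_i + kU_i)` is
#' reported where the rates are nonzero and `NA` below the onset.
#'
#' @param construct A [construct()].
#' @return An object of class `folding_kinetics` with fields `kF`, `kU`,
#'   `P_eq` (vectors of length `M`), `onset` and `M`.
#' @export
build_kinetics <- function(construct) {
  stopifnot(inherits(construct, "construct"))
  M <- construct$M
  onset <- construct$onset
  kF <- numeric(M); kU <- numeric(M)
  kF[onset:M] <- construct$bulk_kF
  kU[onset:M] <- construct$bulk_kU
  P_eq <- rep(NA_real_, M)
  P_eq[onset:M] <- construct$bulk_kF / (construct$bulk_kF + construct$bulk_kU)
  structure(list(kF = kF, kU = kU, P_eq = P_eq, onset = onset, M = M),
            class = "folding_kinetics")
}

#' Renumber multi-segment domain definitions into contiguous domains
#'
#' External domain databases can define a single domain as several
#' non-contiguous residue segments. This routine splits every domain into
#' its contiguous segments, discards segments that do not exceed
#' `min_length` residues (strictly, by default: a 50-residue segment is
#' dropped under the default `min_length = 50`), and renumbers the
#' survivors sequentially, preserving original domain order and then
#' segment order.
#'
#' @param segments A data frame with columns `domain`, `start`, `end`
#'   (residue indices, 1-based inclusive); one row per contiguous segment.
#' @param min_length Minimum segment length in residues (default 50).
#' @param strict If `TRUE` (default) keep segments of length
#'   `> min_length`; if `FALSE` keep segments of length `>= min_length`.
#' @return A data frame with columns `domain` (new sequential number),
#'   `start`, `end`, `original_domain`.
#' @export
renumber_domains <- function(segments, min_length = 50, strict = TRUE) {
  req <- c("domain", "start", "end")
  if (!is.data.frame(segments) || !all(req %in% names(segments))) {
    stop("`segments` must be a data frame with columns domain, start, end",
         call. = FALSE)
  }
  if (nrow(segments) == 0L) {
    return(data.frame(domain = integer(0), start = integer(0),
                      end = integer(0), original_domain = integer(0)))
  }
  if (any(segments$start > segments$end)) {
    stop("invalid segment: start > end", call. = FALSE)
  }
  # overlapping segments within one original domain are a definition error
  for (d in unique(segments$domain)) {
    seg <- segments[segments$domain == d, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)])) {
      stop(sprintf("overlapping segments within domain %s", d), call. = FALSE)
    }
  }
  ord <- order(match(segments$domain, unique(segments$domain)), segments$start)
  seg <- segments[ord, , drop = FALSE]
  len <- seg$end - seg$start + 1L
  keep <- if (strict) len > min_length else len >= min_length
  seg <- seg[keep, , drop = FALSE]
  data.frame(domain = seq_len(nrow(seg)),
             start = as.integer(seg$start),
             end = as.integer(seg$end),
             original_domain = seg$domain,
             row.names = NULL)
}

#' Observable codon set from labelled residue positions
#'
#' Intersects the assay's labelled residue positions (e.g. Met/Cys codon
#' positions reachable by the radiolabel) with the segment of interest.
#' An empty intersection makes the construct invisible to the assay and
#' triggers a warning.
#'
#' @param labelled_positions Residue/codon indices carrying a detectable
#'   label.
#' @param segment_start,segment_end Codon interval of the segment of
#'   interest (1-based, inclusive).
#' @return Sorted integer vector of observable codon indices.
#' @export
observable_from_labelled <- function(labelled_positions, segment_start,
                                     segment_end) {
  stopifnot(segment_start >= 1, segment_end >= segment_start)
  out <- sort(unique(as.integer(labelled_positions)))
  out <- out[out >= segment_start & out <= segment_end]
  if (length(out) == 0L) {
    warning("no labelled residue falls in the segment of interest; ",
            "the construct is invisible to the assay", call. = FALSE)
  }
  out
}
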