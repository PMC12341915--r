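#' Signal-peptide record
#'
#' A signal peptide with its SignalP-style category and 1-based inclusive
#' N/H/C region spans.  Regions must be contiguous, ordered N -> H -> (C),
#' and together cover `[1, cleavage_pos]`.  LIPO/TATLIPO peptides carry no
#' C-region (the lipobox is treated as an extension of the H-region).
#'
#' @param protein_id Identifier.
#' @param sequence Uppercase one-letter amino-acid string.
#' @param category One of `"SP"`, `"LIPO"`, `"TAT"`, `"TATLIPO"`, `"PILIN"`.
#' @param n,h,c Integer length-2 spans `c(start, end)`; `c` may be `NULL`.
#'   All `NULL` for PILIN (regions are not annotated and such records are
#'   excluded from feature analysis).
#' @param cleavage_pos Final residue index of the signal sequence.
#' @param localization Optional ground-truth/assigned localization label.
#' @return Object of class `signal_peptide`.
#' @export
signal_peptide <- function(protein_id, sequence, category,
                           n = NULL, h = NULL, c = NULL,
                           cleavage_pos = NULL, localization = NA_character_) {
  category <- match.arg(category, c("SP", "LIPO", "TAT", "TATLIPO", "PILIN"))
  sequence <- toupper(sequence)
  .residues(sequence)  # validates alphabet
  regions <- Filter(Negate(is.null), list(n = n, h = h, c = c))
  regions <- lapply(regions, as.integer)
  if (!is.null(cleavage_pos)) cleavage_pos <- as.integer(cleavage_pos)
  if (category != "PILIN") {
    if (is.null(n) || is.null(h))
      stop(protein_id, ": N and H region spans are required for ", category)
    if (category %in% c("LIPO", "TATLIPO") && !is.null(c))
      stop(protein_id, ": ", category, " peptides must not have a C-region")
    if (category %in% c("SP", "TAT") && is.null(c))
      stop(protein_id, ": ", category, " peptides must have a C-region")
    spans <- regions[c("n", "h", if (!is.null(c)) "c")]
    for (nm in names(spans)) {
      s <- spans[[nm]]
      if (length(s) != 2L || s[1L] > s[2L] || s[1L] < 1L)
        stop(protein_id, ": malformed ", nm, "-region span")
    }
    if (is.null(cleavage_pos)) cleavage_pos <- spans[[length(spans)]][2L]
    ends <- vapply(spans, `[`, 0L, 2L)
    starts <- vapply(spans, `[`, 0L, 1L)
    if (starts[1L] != 1L ||
        any(starts[-1L] != utils::head(ends, -1L) + 1L) ||
        ends[length(ends)] != cleavage_pos)
      stop(protein_id,
           ": region spans must be contiguous, ordered and cover ",
           "[1, cleavage_pos]")
    if (cleavage_pos > nchar(sequence))
      stop(protein_id, ": cleavage_pos beyond sequence end")
  }
  structure(list(protein_id = protein_id, sequence = sequence,
                 category = category, regions = regions,
                 cleavage_pos = cleavage_pos, localization = localization),
            class = "signal_peptide")
}

#' @export
print.signal_peptide <- function(x, ...) {
  spans <- vapply(x$regions, function(s) sprintf("%d-%d", s[1L], s[2L]), "")
  cat(sprintf("signal_peptide %s [%s] %s (%s)\n", x$protein_id, x$category,
              x$sequence,
              if (length(spans))
                paste(sprintf("%s:%s", names(spans), spans), collapse = " ")
              else "no regions"))
  invisible(x)
}

#' Per-residue secondary-structure / burial prediction
#'
#' JPred-style per-residue tracks for one signal sequence: a state string
#' over `H` (helix), `E` (strand), `-` (coil); a digit string of prediction
#' confidences 0-9; and burial strings over `B`/`-` at three exposure
#' cutoffs (0, 5 and 25 percent relative solvent accessibility).
#'
#' @param protein_id Identifier.
#' @param states State string.
#' @param conf Confidence digit string, same length.
#' @param burial Named character vector `c(sol0=, sol5=, sol25=)` of
#'   equal-length burial strings.
#' @return Object of class `sspred`.
#' @export
sspred <- function(protein_id, states, conf, burial) {
  L <- nchar(states)
  if (grepl("[^HE-]", states)) stop("states must be over {H, E, -}")
  if (nchar(conf) != L || grepl("[^0-9]", conf))
    stop("conf must be a digit string matching states length")
  if (!all(c("sol0", "sol5", "sol25") %in% names(burial)))
    stop("burial must have entries sol0, sol5, sol25")
  if (any(nchar(burial) != L) || any(grepl("[^B-]", burial)))
    stop("burial strings must be over {B, -} and match states length")
  structure(list(protein_id = protein_id, states = states, conf = conf,
                 burial = burial[c("sol0", "sol5", "sol25")]),
            class = "sspred")
}

#' Load signal peptides from FASTA plus a region-annotation table
#'
#' Reads sequences and their SignalP-6-style region annotations, enforces
#' the span invariants, and applies the analysis filter: PILIN records and
#' signal sequences of length <= 5 are excluded (with a message naming each
#' exclusion).
#'
#' @param fasta_path FASTA of signal-peptide sequences.
#' @param region_path Region TSV (`id`, `category`, `n_start`, `n_end`,
#'   `h_start`, `h_end`, `c_start`, `c_end`, `cleavage_pos`; 1-based
#'   inclusive; NA for absent regions).
#' @param localizations Optional named character vector mapping id ->
#'   localization label.
#' @param quiet Suppress exclusion messages.
#' @return Named list of `signal_peptide` objects that pass the filter.
#' @export
load_signal_annotations <- function(fasta_path, region_path,
                                    localizations = NULL, quiet = FALSE) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  seq_ids <- sub("\\s.*$", "", names(seqs))
  ann <- read_tsv(region_path)
  missing <- setdiff(ann$id, seq_ids)
  if (length(missing))
    stop("region table references sequences absent from FASTA: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(ann))) {
    id <- ann$id[i]
    seq <- as.character(seqs[[match(id, seq_ids)]])
    cat_i <- ann$category[i]
    sig_len <- if (!is.na(ann$cleavage_pos[i])) ann$cleavage_pos[i]
               else nchar(seq)
    if (cat_i == "PILIN") {
      if (!quiet) message("excluded ", id, ": PILIN category")
      next
    }
    if (sig_len <= 5) {
      if (!quiet) message("excluded ", id, ": signal length <= 5")
      next
    }
    span <- function(a, b) {
      if (is.na(ann[[a]][i])) NULL
      else c(as.integer(ann[[a]][i]), as.integer(ann[[b]][i]))
    }
    out[[id]] <- signal_peptide(
      protein_id = id, sequence = seq, category = cat_i,
      n = span("n_start", "n_end"), h = span("h_start", "h_end"),
      c = span("c_start", "c_end"),
      cleavage_pos = as.integer(ann$cleavage_pos[i]),
      localization = if (!is.null(localizations) && id %in% names(localizations))
        localizations[[id]] else NA_character_)
  }
  out
}
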