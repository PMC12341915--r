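#' TSV input/output with provenance headers
#'
#' All tables written by the pipeline are plain TSV with a header row,
#' preceded by `#`-prefixed provenance comment lines (package version, seed,
#' config hash).  Readers skip comment lines, so the files round-trip.
#'
#' @name apexloc_io
#' @keywords internal
NULL

.provenance_lines <- function(seed = NULL, config_hash = NULL) {
  c(sprintf("# apexloc %s", as.character(utils::packageVersion("apexloc"))),
    if (!is.null(seed)) sprintf("# seed=%s", format(seed)),
    if (!is.null(config_hash)) sprintf("# config_hash=%s", config_hash))
}

#' Write a data.frame as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields recorded as comments.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @param colClasses Passed to [utils::read.delim()] (e.g. `"character"`
#'   to protect digit strings with leading zeros).
#' @return data.frame.
#' @export
read_tsv <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = colClasses)
}

#' Write / read an intensity matrix
#'
#' The matrix is stored as a TSV with proteins in rows (first column
#' `protein_id`) and one column per sample; annotations go to a second TSV
#' (`sample_id`, `bait`, `bait_compartment`, `replicate`).
#'
#' @param m An `intensity_matrix`.
#' @param path Matrix TSV path.
#' @param annotation_path Sample-annotation TSV path.
#' @param seed,config_hash Provenance fields.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(m, path, annotation_path,
                                   seed = NULL, config_hash = NULL) {
  if (!inherits(m, "intensity_matrix")) stop("expected an intensity_matrix")
  df <- data.frame(protein_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed, config_hash = config_hash)
  write_tsv(m$samples, annotation_path, seed = seed, config_hash = config_hash)
  invisible(path)
}

#' @rdname write_intensity_matrix
#' @param scale Scale of the stored values (`"intensity"` or `"ln"`).
#' @return For `read_intensity_matrix`, an `intensity_matrix`.
#' @export
read_intensity_matrix <- function(path, annotation_path,
                                  scale = c("intensity", "ln")) {
  scale <- match.arg(scale)
  df <- read_tsv(path)
  if (names(df)[1L] != "protein_id")
    stop("expected first column 'protein_id' in ", path)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$protein_id
  samples <- read_tsv(annotation_path)
  intensity_matrix(values, samples, scale = scale)
}

#' Read control-protein lists
#'
#' Expects columns `protein_id`, `role` (`tp`/`fp`) and `analysis`
#' (`lumen_vs_cyto` / `pom_vs_cyto`).
#'
#' @param path Control-list TSV path.
#' @return Named list of [control_set()] objects, one per analysis present.
#' @export
read_control_sets <- function(path) {
  df <- read_tsv(path)
  req <- c("protein_id", "role", "analysis")
  if (!all(req %in% names(df)))
    stop("control list must have columns: ", paste(req, collapse = ", "))
  out <- lapply(split(df, df$analysis), function(d) {
    control_set(analysis = d$analysis[1L],
                tp_ids = d$protein_id[d$role == "tp"],
                fp_ids = d$protein_id[d$role == "fp"])
  })
  out
}

#' Write signal peptides as FASTA plus a region-annotation TSV
#'
#' The TSV dialect has 1-based inclusive coordinates: `id`, `category`,
#' `n_start`, `n_end`, `h_start`, `h_end`, `c_start`, `c_end`,
#' `cleavage_pos`.  Missing regions (C-region of LIPO/TATLIPO, all regions
#' of PILIN) are `NA`.
#'
#' @param peptides List of `signal_peptide` objects.
#' @param fasta_path FASTA output path.
#' @param region_path Region-annotation TSV output path.
#' @param seed,config_hash Provenance fields.
#' @return `fasta_path`, invisibly.
#' @export
write_signal_peptides <- function(peptides, fasta_path, region_path,
                                  seed = NULL, config_hash = NULL) {
  seqs <- Biostrings::AAStringSet(vapply(peptides, `[[`, "", "sequence"))
  names(seqs) <- vapply(peptides, `[[`, "", "protein_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  span_or_na <- function(p, region, i) {
    s <- p$regions[[region]]
    if (is.null(s)) NA_integer_ else s[i]
  }
  df <- data.frame(
    id = names(seqs),
    category = vapply(peptides, `[[`, "", "category"),
    n_start = vapply(peptides, span_or_na, 0L, "n", 1L),
    n_end   = vapply(peptides, span_or_na, 0L, "n", 2L),
    h_start = vapply(peptides, span_or_na, 0L, "h", 1L),
    h_end   = vapply(peptides, span_or_na, 0L, "h", 2L),
    c_start = vapply(peptides, span_or_na, 0L, "c", 1L),
    c_end   = vapply(peptides, span_or_na, 0L, "c", 2L),
    cleavage_pos = vapply(peptides, function(p)
      if (is.null(p$cleavage_pos)) NA_integer_ else p$cleavage_pos, 0L),
    stringsAsFactors = FALSE)
  write_tsv(df, region_path, seed = seed, config_hash = config_hash)
  invisible(fasta_path)
}

#' Write / read per-residue secondary-structure predictions
#'
#' TSV dialect: `id`, `states` (string over H/E/-), `conf` (string of digits
#' 0-9), `sol0`, `sol5`, `sol25` (burial strings over B/- at 0/5/25 percent
#' exposure cutoffs).
#'
#' @param preds List of `sspred` objects.
#' @param path Output path.
#' @param seed,config_hash Provenance fields.
#' @return `path`, invisibly.
#' @export
write_ss_predictions <- function(preds, path, seed = NULL, config_hash = NULL) {
  df <- data.frame(
    id = vapply(preds, `[[`, "", "protein_id"),
    states = vapply(preds, `[[`, "", "states"),
    conf = vapply(preds, `[[`, "", "conf"),
    sol0 = vapply(preds, function(p) p$burial[["sol0"]], ""),
    sol5 = vapply(preds, function(p) p$burial[["sol5"]], ""),
    sol25 = vapply(preds, function(p) p$burial[["sol25"]], ""),
    stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed, config_hash = config_hash)
  invisible(path)
}

#' @rdname write_ss_predictions
#' @return For `read_ss_predictions`, a named list of `sspred` objects.
#' @export
read_ss_predictions <- function(path) {
  # everything as character: confidence strings may carry leading zeros
  df <- read_tsv(path, colClasses = "character")
  preds <- lapply(seq_len(nrow(df)), function(i) {
    sspred(protein_id = df$id[i],
           states = as.character(df$states[i]),
           conf = as.character(df$conf[i]),
           burial = c(sol0 = as.character(df$sol0[i]),
                      sol5 = as.character(df$sol5[i]),
                      sol25 = as.character(df$sol25[i])))
  })
  names(preds) <- df$id
  preds
}

#' Parse a JPred-style concise prediction file
#'
#' Reads the `key:val1,val2,...` concise format (`jnetpred`, `JNETCONF`,
#' `JNETSOL0`, `JNETSOL5`, `JNETSOL25` records) for a single sequence and
#' returns an `sspred`.
#'
#' @param path Path to a concise-format file.
#' @param protein_id Identifier to attach.
#' @return An `sspred` object.
#' @export
read_jpred_concise <- function(path, protein_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & grepl(":", lines, fixed = TRUE)]
  fields <- list()
  for (ln in lines) {
    key <- sub(":.*$", "", ln)
    vals <- strsplit(sub("^[^:]*:", "", ln), ",", fixed = TRUE)[[1L]]
    vals <- vals[nzchar(vals)]
    fields[[key]] <- vals
  }
  need <- c("jnetpred", "JNETCONF")
  if (!all(need %in% names(fields)))
    stop("concise file lacks records: ",
         paste(setdiff(need, names(fields)), collapse = ", "))
  states <- fields$jnetpred
  states[!states %in% c("H", "E")] <- "-"
  sol <- function(key) {
    if (is.null(fields[[key]])) strrep("-", length(states))
    else paste(ifelse(fields[[key]] == "B", "B", "-"), collapse = "")
  }
  sspred(protein_id = protein_id,
         states = paste(states, collapse = ""),
         conf = paste(fields$JNETCONF, collapse = ""),
         burial = c(sol0 = sol("JNETSOL0"), sol5 = sol("JNETSOL5"),
                    sol25 = sol("JNETSOL25")))
}

# md5 of a serialized R object, for config hashes in provenance headers
.config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
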