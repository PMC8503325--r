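# Readers/writers for every external representation: FASTA and AIRR
# rearrangement TSV sequence sets, PSSM TSV + JSON sidecar, FR-score report
# TSV, and peptide:MHC-II KD tables.

PSSM_FORMAT_VERSION <- "1.0"

#' Normalize a V-call to a gene-level name
#'
#' Maps annotation-style V calls such as `"IGHV3-23*01"` onto the gene-level
#' naming used throughout the package (`"VH3-23"`), stripping the `IGH` locus
#' prefix and the allele suffix. The allele name, when present, is retained
#' under the same convention (`"VH3-23*01"`).
#'
#' @param v_call Character vector of V calls (e.g. AIRR `v_call` values).
#' @return Data frame with columns `gene` and `allele` (allele `NA` when the
#'   call carries none).
#' @export
normalize_v_call <- function(v_call) {
  gene_allele <- sub("^IGH", "", v_call)          # IGHV3-23*01 -> V3-23*01
  gene_allele <- sub("^V", "VH", gene_allele)     # V3-23*01    -> VH3-23*01
  gene <- sub("\\*.*$", "", gene_allele)
  allele <- ifelse(grepl("\\*", gene_allele), gene_allele, NA_character_)
  data.frame(gene = gene, allele = allele)
}

#' Construct a repertoire set
#'
#' @param records Data frame with at least `sequence_id` and `nt_seq`;
#'   optional `subject_id`, `isotype` (one of `IgG`, `IgM`, `other`) and
#'   `germline_gene`.
#' @param germline Gene-level germline name shared by all records, or `NA`
#'   when unassigned.
#' @return Object of class `repertoire_set`.
#' @export
repertoire_set <- function(records, germline = NA_character_) {
  stopifnot(is.data.frame(records),
            all(c("sequence_id", "nt_seq") %in% names(records)))
  for (col in c("subject_id", "isotype", "germline_gene"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  records$nt_seq <- toupper(records$nt_seq)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", records$nt_seq)
  if (any(bad))
    stop("record(s) contain characters outside the IUPAC nucleotide alphabet: ",
         paste(head(records$sequence_id[bad], 3), collapse = ", "))
  records$ambiguous <- grepl("[^ACGT]", records$nt_seq)
  genes <- unique(records$germline_gene[!is.na(records$germline_gene)])
  if (length(genes) > 1)
    stop("records carry more than one assigned germline gene: ",
         paste(genes, collapse = ", "))
  if (is.na(germline) && length(genes) == 1) germline <- genes
  iso <- records$isotype
  iso[!is.na(iso) & !iso %in% c("IgG", "IgM")] <- "other"
  records$isotype <- iso
  structure(list(germline = germline, records = records), class = "repertoire_set")
}

#' @export
print.repertoire_set <- function(x, ...) {
  cat("<repertoire_set> ", nrow(x$records), " records; germline: ",
      ifelse(is.na(x$germline), "(unassigned)", x$germline), "\n", sep = "")
  invisible(x)
}

#' Read repertoire sequences from FASTA or AIRR rearrangement TSV
#'
#' FASTA records become `(sequence_id, nt_seq)` pairs; AIRR input must carry
#' at least `sequence_id` and `sequence` columns, and its `v_call` (when
#' present) populates the germline assignment via [normalize_v_call()].
#' Sequences are uppercased; IUPAC ambiguity codes are accepted and flagged
#' per record in the `ambiguous` column, anything else is an error.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"airr"`.
#' @return A [repertoire_set()].
#' @export
read_sequences <- function(path, format = c("fasta", "airr")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    nonempty <- which(nzchar(trimws(lines)))
    if (!length(nonempty)) stop("empty FASTA file: ", path)
    if (!startsWith(trimws(lines[nonempty[1]]), ">"))
      stop("malformed FASTA: line ", nonempty[1], " is not a header in ", path)
    hdr <- grepl("^>", lines)
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(gsub("\\s", "", x), collapse = ""), "")
    if (any(!nzchar(seqs))) {
      at <- which(!nzchar(seqs))[1]
      stop("malformed FASTA: record '", ids[at], "' has no sequence lines")
    }
    rec <- data.frame(sequence_id = ids, nt_seq = unname(seqs))
    repertoire_set(rec)
  } else {
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (!nrow(tab)) stop("empty AIRR file: ", path)
    need <- c("sequence_id", "sequence")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("AIRR input lacks required column(s): ", paste(miss, collapse = ", "))
    rec <- data.frame(sequence_id = tab$sequence_id, nt_seq = tab$sequence)
    if (!is.null(tab$subject_id)) rec$subject_id <- tab$subject_id
    if (!is.null(tab$isotype)) rec$isotype <- tab$isotype
    if (!is.null(tab$v_call)) rec$germline_gene <- normalize_v_call(tab$v_call)$gene
    repertoire_set(rec)
  }
}

#' Write a repertoire set
#'
#' `write_fasta()` writes plain nucleotide FASTA (one header per
#' `sequence_id`); `write_airr()` writes a minimal AIRR rearrangement TSV
#' with `sequence_id`, `sequence` and, when known, `v_call`, `subject_id`
#' and `isotype`.
#'
#' @param x A [repertoire_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "repertoire_set"))
  out <- rbind(paste0(">", x$records$sequence_id), x$records$nt_seq)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_airr <- function(x, path) {
  stopifnot(inherits(x, "repertoire_set"))
  tab <- data.frame(sequence_id = x$records$sequence_id,
                    sequence = x$records$nt_seq)
  if (!all(is.na(x$records$germline_gene)))
    tab$v_call <- sub("^VH", "IGHV", x$records$germline_gene)
  if (!all(is.na(x$records$subject_id))) tab$subject_id <- x$records$subject_id
  if (!all(is.na(x$records$isotype))) tab$isotype <- x$records$isotype
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a PSSM as TSV plus JSON sidecar
#'
#' The TSV holds one row per framework position (columns `position`, `region`,
#' `wt`, then the 20 amino acids alphabetically); masked cells (wild-type and
#' allelic residues) are written as `NA`, never as a numeric score. Scores are
#' written with 6 decimal places. The sidecar `<path>.json` records the format
#' version, germline name, centering constant `alpha`, log base, sequence
#' count and filter settings, so that `read_pssm(write_pssm(p))` reproduces
#' scores to 6 decimals and metadata exactly.
#'
#' @param pssm A `pssm` object (see [score_matrix()]).
#' @param path Output TSV path; the sidecar is written next to it.
#' @return `path`, invisibly (`write_pssm`); a `pssm` (`read_pssm`).
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"), length(pssm$positions) >= 1)
  sc <- pssm$scores
  fmt <- matrix(sprintf("%.6f", sc), nrow = nrow(sc))
  fmt[is.na(sc)] <- "NA"
  tab <- data.frame(position = pssm$positions, region = pssm$region,
                    wt = pssm$wt, fmt, check.names = FALSE)
  names(tab)[-(1:3)] <- AA20
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(format_version = PSSM_FORMAT_VERSION,
               germline = pssm$germline,
               alpha = pssm$alpha,
               log_base = pssm$log_base,
               n_sequences = pssm$n_sequences,
               filter = pssm$filter)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("PSSM sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$format_version, PSSM_FORMAT_VERSION))
    stop("incompatible PSSM file: sidecar format_version '",
         meta$format_version, "' (this build reads '", PSSM_FORMAT_VERSION, "')")
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  scores <- as.matrix(tab[, AA20])
  dimnames(scores) <- list(tab$position, AA20)
  new_pssm(germline = meta$germline, positions = tab$position,
           region = tab$region, wt = tab$wt, scores = scores,
           alpha = as.numeric(meta$alpha),
           n_sequences = as.integer(meta$n_sequences),
           filter = meta$filter)
}

#' Write an FR-score report as TSV
#'
#' @param report Data frame from [score_report()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide:MHC-II KD prediction table
#'
#' Accepts any TSV carrying `peptide` (15-mer amino-acid string), `allele`
#' (e.g. `"DRB1*04:01"`) and `kd_nM` (positive, nanomolar) columns; extra
#' columns are kept. This is the adapter for external MHC-II affinity
#' predictors, whose execution is out of scope.
#'
#' @param path Input TSV.
#' @return Data frame with validated `peptide`, `allele`, `kd_nM`.
#' @export
read_kd_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "kd_nM")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("KD table lacks column(s): ", paste(miss, collapse = ", "))
  validate_kd_table(tab)
  tab
}

validate_kd_table <- function(tab) {
  if (any(nchar(tab$peptide) != 15L))
    stop("KD table peptides must be 15-mers")
  if (any(!is.finite(tab$kd_nM)) || any(tab$kd_nM <= 0))
    stop("KD values must be positive and finite (nM)")
  invisible(tab)
}

#' @rdname read_kd_table
#' @param tab KD table to write.
#' @param path Output TSV.
#' @export
write_kd_table <- function(tab, path) {
  validate_kd_table(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
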