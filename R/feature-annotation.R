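# Ingestion of annotated gene models: GFF3 + protein FASTA, HMM domain-hit
# tables (CAZy + Pfam models), and signal-peptide flags. Coordinates are
# GFF3 1-based inclusive at I/O and 0-based half-open internally.

#' Load gene features from GFF3 and their protein sequences from FASTA
#'
#' Reads protein-coding features (types `CDS` or `gene`; `CDS` preferred when
#' both are present for a locus tag) and attaches protein lengths from the
#' FASTA. GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; features are sorted by (contig, start).
#'
#' @param gff3_path Path to a GFF3 file whose CDS/gene features carry a
#'   `locus_tag` attribute.
#' @param fasta_path Path to a protein FASTA keyed by locus tag.
#' @return A data frame (`gene_features`) with columns `contig`, `locus_tag`,
#'   `start`, `end` (0-based half-open), `strand`, `protein_length`.
#' @export
load_features <- function(gff3_path, fasta_path) {
  .check_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  if (!length(gr)) stop("no CDS/gene features found in ", gff3_path)
  tags <- S4Vectors::mcols(gr)$locus_tag
  if (is.null(tags) || anyNA(tags))
    stop("every CDS/gene feature must carry a locus_tag attribute")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    locus_tag = as.character(tags),
    start = GenomicRanges::start(gr) - 1L,  # 1-based incl. -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  # prefer CDS rows on duplicate locus tags (gene + CDS for the same locus)
  type <- as.character(gr$type)
  df <- df[order(df$locus_tag, type != "CDS"), ]
  df <- df[!duplicated(df$locus_tag), ]
  prot <- Biostrings::readAAStringSet(fasta_path)
  names(prot) <- sub("\\s.*$", "", names(prot))
  missing <- setdiff(df$locus_tag, names(prot))
  if (length(missing))
    stop("protein sequence missing from FASTA for locus tag(s): ",
         paste(missing, collapse = ", "))
  df$protein_length <- Biostrings::width(prot)[match(df$locus_tag, names(prot))]
  if (any(df$protein_length <= 0)) stop("zero-length protein sequence found")
  df <- df[order(df$contig, df$start), ]
  rownames(df) <- NULL
  class(df) <- c("gene_features", "data.frame")
  df
}

.check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nf != 9L]
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1]], ")")
  invisible(TRUE)
}

#' Load and filter domain hits from a tab-separated hit table
#'
#' The table carries one row per (protein, model) hit with columns
#' `locus_tag, model, e_value, coverage, ali_from, ali_to` (a condensed
#' domtblout dialect). Hits failing either cutoff are dropped; model names
#' are normalized: a trailing `.hmm` is stripped and CAZy family tokens
#' (gh/ce/pl/cbm + number) are uppercased.
#'
#' @param path Hit table path (tab-separated, no header or `#` comments).
#' @param evalue_cutoff Maximal e-value retained (default 1e-5).
#' @param coverage_cutoff Minimal model coverage retained (default 0.35,
#'   the dbCAN-style convention for CAZy HMM scans).
#' @return Data frame of surviving hits with normalized `model` names.
#' @export
load_domain_hits <- function(path, evalue_cutoff = 1e-5,
                             coverage_cutoff = 0.35) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  if (!length(body))
    return(data.frame(locus_tag = character(0), model = character(0),
                      e_value = numeric(0), coverage = numeric(0),
                      ali_from = integer(0), ali_to = integer(0)))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 6L))
    stop("unparseable hit-table row at line ", body[which(nf != 6L)[1]],
         " in ", path, " (expected 6 tab-separated fields)")
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  hits <- data.frame(locus_tag = m[, 1], model = m[, 2],
                     e_value = suppressWarnings(as.numeric(m[, 3])),
                     coverage = suppressWarnings(as.numeric(m[, 4])),
                     ali_from = suppressWarnings(as.integer(m[, 5])),
                     ali_to = suppressWarnings(as.integer(m[, 6])),
                     stringsAsFactors = FALSE)
  bad <- which(is.na(hits$e_value) | is.na(hits$coverage))
  if (length(bad))
    stop("unparseable hit-table row at line ", body[bad[1]], " in ", path)
  if (any(hits$e_value < 0)) stop("negative e-value in hit table")
  if (any(hits$coverage < 0 | hits$coverage > 1))
    stop("coverage must lie in [0, 1]")
  hits$model <- normalize_model_name(hits$model)
  hits <- hits[hits$e_value <= evalue_cutoff &
                 hits$coverage >= coverage_cutoff, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Normalize a domain model name
#'
#' Strips a trailing `.hmm` and uppercases CAZy family tokens
#' (e.g. `"gh10.hmm"` becomes `"GH10"`). Other names are left as-is.
#'
#' @param model Character vector of model names.
#' @return Normalized character vector.
#' @export
normalize_model_name <- function(model) {
  model <- sub("\\.hmm$", "", model, ignore.case = TRUE)
  cazy <- grepl("^(gh|ce|pl|cbm|aa|gt)[0-9]+(_[0-9]+)?$", model,
                ignore.case = TRUE)
  model[cazy] <- toupper(model[cazy])
  model
}

.cazy_label_pattern <- "^(GH|CE|PL|CBM)[0-9]+(_[0-9]+)?$"
.pfam_pattern <- "^PF[0-9]{5}(\\.[0-9]+)?$"

#' Default routing of domain models to gene labels
#'
#' SusC-like transporter models map to `SUSC`, SusD-like surface-binding
#' models to `SUSD`, CAZy family models to their own family token. Pfam
#' accessions (`PFxxxxx`) never produce a label: they are recorded as domain
#' evidence only, so a protein whose sole hits are Pfam domains remains a
#' PUF (proteins of unknown function frequently carry fold-level Pfam
#' domains without an assignable function). Any other named model is taken
#' as a known non-PUL-related function and mapped to `OTHER` unless the map
#' routes it elsewhere.
#'
#' @param susc_models,susd_models Model names routed to SUSC / SUSD.
#' @param other Named character vector of extra model-to-label routes.
#' @return A `label_map` list consumed by [assign_labels()].
#' @export
default_label_map <- function(susc_models = c("SusC", "TonB_dep_Rec"),
                              susd_models = c("SusD", "SusD-like"),
                              other = character(0)) {
  structure(list(susc_models = susc_models, susd_models = susd_models,
                 other = other), class = "label_map")
}

#' Assign functional labels to gene features
#'
#' Routes each feature's surviving domain hits through the label map and
#' attaches signal-peptide flags. A feature acquiring no functional label
#' (no SusC/SusD, no CAZy family, no other named function) is labelled
#' `PUF`; Pfam accessions are kept as domain evidence but do not lift PUF
#' status. Features may carry several labels (multi-domain CAZymes).
#' Re-running the assignment on its own output is a no-op.
#'
#' @param features Output of [load_features()].
#' @param hits Output of [load_domain_hits()].
#' @param signal Data frame `(locus_tag, signal)` of 0/1 signal-peptide
#'   flags (e.g. parsed SignalP calls); absent tags default to 0.
#' @param label_map A [default_label_map()].
#' @return `features` with list-columns `labels` and `pfam` plus logical
#'   `signal_peptide`.
#' @export
assign_labels <- function(features, hits, signal = NULL,
                          label_map = default_label_map()) {
  stopifnot(is.data.frame(features))
  unknown <- setdiff(unique(hits$locus_tag), features$locus_tag)
  if (length(unknown))
    stop("domain hit(s) reference unknown locus tag(s): ",
         paste(unknown, collapse = ", "))
  hit_split <- split(hits$model, hits$locus_tag)
  route <- function(models) {
    labels <- character(0)
    pfam <- models[grepl(.pfam_pattern, models)]
    rest <- setdiff(models, pfam)
    labels <- c(labels,
                if (any(rest %in% label_map$susc_models)) "SUSC",
                if (any(rest %in% label_map$susd_models)) "SUSD")
    labels <- c(labels, rest[grepl(.cazy_label_pattern, rest)])
    mapped <- rest %in% names(label_map$other)
    labels <- c(labels, unname(label_map$other[rest[mapped]]))
    leftover <- rest[!(rest %in% c(label_map$susc_models, label_map$susd_models)) &
                       !grepl(.cazy_label_pattern, rest) & !mapped]
    if (length(leftover)) labels <- c(labels, "OTHER")
    if (!length(labels)) labels <- "PUF"
    list(labels = unique(labels), pfam = unique(pfam))
  }
  routed <- lapply(features$locus_tag, function(tag) {
    models <- hit_split[[tag]]
    if (is.null(models)) list(labels = "PUF", pfam = character(0))
    else route(models)
  })
  features$labels <- lapply(routed, `[[`, "labels")
  features$pfam <- lapply(routed, `[[`, "pfam")
  sp <- rep(FALSE, nrow(features))
  if (!is.null(signal)) {
    names(signal)[1:2] <- c("locus_tag", "signal")
    idx <- match(features$locus_tag, signal$locus_tag)
    sp <- !is.na(idx) & signal$signal[idx] > 0
  }
  features$signal_peptide <- sp
  class(features) <- c("gene_features", "data.frame")
  features
}

#' Read a two-column signal-peptide flag table
#'
#' @param path Tab-separated file `(locus_tag, 0/1)`, optional header.
#' @return Data frame with columns `locus_tag`, `signal`.
#' @export
read_signal_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("locus", first, ignore.case = TRUE)
  tab <- read.table(path, header = has_header, sep = "\t",
                    stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("locus_tag", "signal")
  tab
}
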