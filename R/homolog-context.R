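# Classification of homolog-search hits by PUL genomic context, score-group
# partitioning, and clade/context concordance on a supplied phylogeny.
# Alignment and tree inference are upstream, external steps; their outputs
# (BLAST tabular, newick) are consumed here.

.blast12_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Load BLAST hits and classify them by PUL genomic context
#'
#' Reads a 12-column BLAST tabular file (outfmt 6), retains hits passing the
#' e-value threshold, sorts by bit score (descending) and keeps at most
#' `top_n`. Each retained subject is joined to a context table mapping locus
#' tags to their PUL membership and predicted substrate; unmapped subjects
#' (or subjects outside any PUL) are classed `no-PUL`. The query's own
#' self-hit, if present, is retained like any other record.
#'
#' @param blast_path BLAST tabular path (qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore).
#' @param evalue_max Retention threshold on e-value (default 1e-10).
#' @param top_n Maximal number of records retained (default 200).
#' @param context Context table: data frame or TSV path with columns
#'   `locus_tag, genome, in_pul, substrate, confidence`.
#' @return Data frame of `HomologRecord`s sorted by descending bit score:
#'   `subject, genome, pident, e_value, bit_score, context_class,
#'   confidence, group` (`group` is `NA` until [partition_groups()]).
#' @export
load_and_classify <- function(blast_path, evalue_max = 1e-10, top_n = 200,
                              context = NULL) {
  nf <- count.fields(blast_path, sep = "\t", comment.char = "#")
  bad <- which(nf != 12L)
  if (length(bad))
    stop("malformed BLAST tabular row at line ", bad[1], " in ", blast_path,
         " (expected 12 tab-separated columns, found ", nf[bad[1]], ")")
  hits <- read.table(blast_path, sep = "\t", col.names = .blast12_cols,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  hits <- hits[order(-hits$bitscore, hits$sseqid), , drop = FALSE]
  hits <- head(hits, top_n)
  ctx <- if (is.character(context)) read_context_table(context) else context
  rec <- data.frame(subject = hits$sseqid, genome = NA_character_,
                    pident = hits$pident, e_value = hits$evalue,
                    bit_score = hits$bitscore,
                    context_class = "no-PUL", confidence = NA_character_,
                    group = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(ctx)) {
    idx <- match(rec$subject, ctx$locus_tag)
    mapped <- !is.na(idx)
    rec$genome[mapped] <- ctx$genome[idx[mapped]]
    rec$confidence[mapped] <- ctx$confidence[idx[mapped]]
    in_pul <- mapped & as.logical(ctx$in_pul[idx])
    sub <- tolower(ctx$substrate[idx])
    rec$context_class[in_pul] <- ifelse(
      sub[in_pul] == "xylan", "xylan-PUL",
      ifelse(sub[in_pul] == "alginate", "alginate-PUL", "other-PUL"))
  }
  rownames(rec) <- NULL
  rec
}

#' Read a homolog genomic-context table
#'
#' @param path TSV with header columns `locus_tag, genome, in_pul,
#'   substrate, confidence`.
#' @return Data frame.
#' @export
read_context_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("locus_tag", "genome", "in_pul", "substrate", "confidence")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("context table missing column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Partition homolog records into score groups
#'
#' The `"gap"` method sorts bit scores in decreasing order and splits at the
#' largest adjacent drop, provided that drop exceeds `k` times the median
#' adjacent drop; otherwise all records form a single group. Group 1 is the
#' higher-scoring side. The `"threshold"` method splits at an explicit bit
#' score; `"preset"` passes through a `group` column already present on the
#' records (e.g. curated group labels). Group assignment depends only on the
#' scores, never on input order.
#'
#' @param records Data frame with a `bit_score` column (and `group` for
#'   `"preset"`).
#' @param method `"gap"`, `"threshold"` or `"preset"`.
#' @param k Significance factor for the gap method (default 3).
#' @param threshold Bit score cut for the threshold method (group 1 is
#'   `bit_score >= threshold`).
#' @return `records` with the `group` column filled (integer, 1 = top).
#' @export
partition_groups <- function(records, method = c("gap", "threshold", "preset"),
                             k = 3, threshold = NULL) {
  method <- match.arg(method)
  if (!nrow(records)) stop("no records to partition")
  if (method == "preset") {
    if (!("group" %in% names(records)) || anyNA(records$group))
      stop("preset method requires a complete 'group' column")
    records$group <- as.integer(records$group)
    return(records)
  }
  if (method == "threshold") {
    if (is.null(threshold)) stop("threshold method requires 'threshold'")
    records$group <- ifelse(records$bit_score >= threshold, 1L, 2L)
    return(records)
  }
  if (nrow(records) < 2) stop("gap method needs at least 2 records")
  s <- sort(records$bit_score, decreasing = TRUE)
  drops <- -diff(s)
  i_max <- which.max(drops)
  med <- median(drops)
  if (drops[i_max] > 0 && drops[i_max] > k * med) {
    cut <- (s[i_max] + s[i_max + 1]) / 2
    records$group <- ifelse(records$bit_score > cut, 1L, 2L)
  } else {
    records$group <- 1L
  }
  records
}

#' Test clade/context concordance for one context class on a phylogeny
#'
#' The target class is monophyletic iff the smallest clade containing all
#' its leaves contains only its leaves. The tree is used as rooted at its
#' parsed root; pass `outgroup` to re-root first.
#'
#' @param tree A newick path or an `ape::phylo` object. Every leaf must
#'   appear in `classes`.
#' @param classes Named character vector (leaf label to class), or a
#'   two-column data frame / TSV path.
#' @param target Target class, e.g. `"xylan-PUL"`.
#' @param outgroup Optional leaf label(s) to re-root at before testing.
#' @return A `clade_report`: `target`, `is_monophyletic`, `clade_leaves`
#'   (leaves of the smallest containing clade), `inside` / `outside` counts
#'   (which sum to the clade size).
#' @export
clade_consistency <- function(tree, classes, target, outgroup = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  cls <- .leaf_classes(classes)
  missing <- setdiff(tree$tip.label, names(cls))
  if (length(missing))
    stop("leaf missing from class map: ", paste(missing, collapse = ", "))
  targets <- tree$tip.label[cls[tree$tip.label] == target]
  if (!length(targets))
    stop("no leaf carries target class '", target, "'")
  if (length(targets) == 1L) {
    clade <- targets
  } else {
    node <- ape::getMRCA(tree, targets)
    clade <- ape::extract.clade(tree, node)$tip.label
  }
  inside <- sum(cls[clade] == target)
  outside <- length(clade) - inside
  structure(list(target = target,
                 is_monophyletic = outside == 0L,
                 clade_leaves = clade,
                 inside = inside, outside = outside),
            class = "clade_report")
}

.leaf_classes <- function(classes) {
  if (is.character(classes) && length(classes) == 1L && file.exists(classes))
    classes <- read.table(classes, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (is.data.frame(classes))
    classes <- setNames(as.character(classes[[2]]), classes[[1]])
  if (is.null(names(classes)))
    stop("classes must map leaf labels to class labels")
  classes
}

#' @export
print.clade_report <- function(x, ...) {
  cat(sprintf("<clade report> target '%s': %s\n", x$target,
              if (x$is_monophyletic) "monophyletic" else "NOT monophyletic"))
  cat(sprintf("  smallest containing clade: %d leaves (%d target, %d other)\n",
              length(x$clade_leaves), x$inside, x$outside))
  invisible(x)
}
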