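# susD-anchored PUL detection, substrate inference from CAZyme content,
# candidate triage and deduplication.
#
# Detection follows the relaxed rule for fragmentary metagenome assemblies:
# a cluster needs a susD gene to seed it, not necessarily susC. Strand is
# ignored; a PUL is a physical run of genes on one contig.

#' Default extendable label classes for PUL extension
#'
#' SUSC, SUSD, any CAZy family (GH/CE/PL/CBM) and PUF. Genes with other
#' known functions (label `OTHER`) interrupt a cluster, subject to the gap
#' tolerance.
#'
#' @param labels Character vector of labels for one gene.
#' @return Logical: is the gene extendable (PUL member material)?
#' @export
is_extendable_label <- function(labels) {
  any(labels %in% c("SUSC", "SUSD", "PUF") |
        grepl(.cazy_label_pattern, labels))
}

#' Default xylan/alginate substrate signature configuration
#'
#' A substrate signature is a CAZy family set plus the minimum number of
#' distinct families from that set that must be present. The xylan signature
#' covers backbone- and side-chain-acting families GH10, GH11, GH43, GH51,
#' GH115 plus the esterase family CE1; the alginate signature uses the
#' canonical alginate-lyase PL families. `priority` breaks ties between
#' substrates met with equal distinct-family counts.
#'
#' @return A list with `substrates` (named list of `families`,
#'   `min_families`) and `priority`.
#' @export
default_signatures <- function() {
  list(
    substrates = list(
      xylan = list(families = c("GH10", "GH11", "GH43", "GH51", "GH115", "CE1"),
                   min_families = 2L),
      alginate = list(families = c("PL6", "PL7", "PL15", "PL17"),
                      min_families = 2L)),
    priority = c("xylan", "alginate"))
}

#' Detect susD-anchored polysaccharide utilization loci
#'
#' Every SUSD gene seeds a candidate locus; extension walks left and right
#' along the gene order absorbing genes whose labels are extendable,
#' tolerating at most `max_gap` consecutive non-member genes between
#' members. A locus starts and ends on a member gene; seeds whose extensions
#' meet yield a single merged locus. Completeness flags turn `FALSE` on a
#' side where fewer than `max_gap + 1` genes separate the locus from the
#' contig margin, i.e. where the assembly ends before extension could be
#' ruled out.
#'
#' @param features Labelled features from [assign_labels()].
#' @param max_gap Maximal number of consecutive non-member genes absorbed
#'   inside a locus (default 1; PUL predictions routinely tolerate an
#'   occasional unrelated insertion).
#' @param extendable Predicate on a gene's label vector (default
#'   [is_extendable_label()]).
#' @param require_susc Drop loci lacking a SUSC member (default `FALSE`, the
#'   relaxed rule for fragmentary assemblies).
#' @return List of `pul` objects (possibly empty). Each has `id`, `contig`,
#'   `genes` (the contiguous feature rows, including absorbed gap genes),
#'   `anchors` (`susd`/`susc` positions within the locus), `complete_left`,
#'   `complete_right`, and `substrate`/`evidence` slots filled by
#'   [infer_substrate()].
#' @export
detect_puls <- function(features, max_gap = 1, extendable = is_extendable_label,
                        require_susc = FALSE) {
  stopifnot(is.data.frame(features), "labels" %in% names(features))
  out <- list()
  for (ctg in unique(features$contig)) {
    f <- features[features$contig == ctg, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    n <- nrow(f)
    memb <- vapply(f$labels, extendable, logical(1))
    is_susd <- vapply(f$labels, function(l) "SUSD" %in% l, logical(1))
    seeds <- which(is_susd)
    if (!length(seeds)) next
    windows <- unique(lapply(seeds, function(s) .extend_window(memb, s, max_gap)))
    for (w in windows) {
      genes <- f[w$start:w$end, , drop = FALSE]
      rownames(genes) <- NULL
      rel_susd <- which(vapply(genes$labels, function(l) "SUSD" %in% l, logical(1)))
      rel_susc <- which(vapply(genes$labels, function(l) "SUSC" %in% l, logical(1)))
      if (require_susc && !length(rel_susc)) next
      pul <- structure(list(
        id = NA_character_, contig = ctg, genes = genes,
        anchors = list(susd = rel_susd, susc = rel_susc),
        complete_left = (w$start - 1L) > max_gap,
        complete_right = (n - w$end) > max_gap,
        substrate = NA_character_, evidence = NULL), class = "pul")
      out[[length(out) + 1L]] <- pul
    }
  }
  for (i in seq_along(out))
    out[[i]]$id <- sprintf("PUL_%s_%d", out[[i]]$contig,
                           sum(vapply(out[seq_len(i)], function(p)
                             p$contig == out[[i]]$contig, logical(1))))
  out
}

# Greedy bidirectional extension; returns the unique maximal window (gene
# indices on the contig) containing the seed, trimmed to member genes.
.extend_window <- function(memb, seed, g) {
  n <- length(memb)
  right <- seed; i <- seed + 1L; run <- 0L
  while (i <= n) {
    if (memb[i]) { right <- i; run <- 0L }
    else { run <- run + 1L; if (run > g) break }
    i <- i + 1L
  }
  left <- seed; i <- seed - 1L; run <- 0L
  while (i >= 1L) {
    if (memb[i]) { left <- i; run <- 0L }
    else { run <- run + 1L; if (run > g) break }
    i <- i - 1L
  }
  list(start = left, end = right)
}

#' @export
print.pul <- function(x, ...) {
  labs <- vapply(x$genes$labels, function(l) paste(l, collapse = "+"),
                 character(1))
  cat(sprintf("<PUL %s> %s:%d-%d (%d genes)%s%s\n", x$id, x$contig,
              min(x$genes$start), max(x$genes$end), nrow(x$genes),
              if (!x$complete_left) " [open left]" else "",
              if (!x$complete_right) " [open right]" else ""))
  cat("  genes:", paste(labs, collapse = " "), "\n")
  if (!is.na(x$substrate)) cat("  substrate:", x$substrate, "\n")
  invisible(x)
}

#' Infer the glycan target of a PUL from its CAZyme content
#'
#' Counts the distinct signature families present among member labels for
#' each configured substrate; the locus is assigned the substrate whose
#' signature is met, `"unknown"` if none. If several signatures are met the
#' one with more distinct families present wins, remaining ties broken by
#' the configured priority order (required whenever signature family sets
#' overlap).
#'
#' @param pul A `pul` object (or a list of them, which is mapped over).
#' @param signatures A [default_signatures()]-shaped configuration.
#' @return The `pul` with `substrate` set and `evidence` (a data frame of
#'   signature `family`, gene `count`) attached.
#' @export
infer_substrate <- function(pul, signatures = default_signatures()) {
  if (!inherits(pul, "pul") && is.list(pul))
    return(lapply(pul, infer_substrate, signatures = signatures))
  subs <- signatures$substrates
  fams <- lapply(subs, `[[`, "families")
  overlap <- any(duplicated(unlist(fams)))
  if (overlap && is.null(signatures$priority))
    stop("signature family sets overlap: a priority order is required")
  labels <- unlist(pul$genes$labels)
  met <- list()
  for (s in names(subs)) {
    present <- intersect(subs[[s]]$families, labels)
    if (length(present) >= subs[[s]]$min_families)
      met[[s]] <- length(present)
  }
  if (!length(met)) {
    pul$substrate <- "unknown"
    pul$evidence <- data.frame(family = character(0), count = integer(0))
    return(pul)
  }
  best_n <- max(unlist(met))
  cands <- names(met)[unlist(met) == best_n]
  pick <- if (length(cands) == 1L) cands else {
    pr <- intersect(signatures$priority, cands)
    if (!length(pr)) stop("tie between substrates ",
                          paste(cands, collapse = ", "),
                          " not resolved by priority order")
    pr[1]
  }
  present <- intersect(subs[[pick]]$families, labels)
  pul$substrate <- pick
  pul$evidence <- data.frame(
    family = present,
    count = vapply(present, function(fm)
      sum(vapply(pul$genes$labels, function(l) fm %in% l, logical(1))),
      integer(1)),
    row.names = NULL)
  pul
}

#' Triage PULs into candidate reports with a PUF shortlist
#'
#' Applies the candidate filter - at least `min_proteins` predicted proteins
#' and at least `min_signature` genes carrying a signature CAZy family - and
#' reports, for each passing locus, the proteins of unknown function with
#' the triage evidence used to rank them: signal-peptide flag, Pfam domain
#' accessions, and protein length. A missing signal peptide ranks a PUF
#' down, it does not exclude it.
#'
#' @param puls List of `pul` objects with substrate inference already run.
#' @param min_proteins Minimal number of predicted proteins (default 5).
#' @param min_signature Minimal number of genes with a signature-family
#'   label (default 2).
#' @param signature_families Families counted toward `min_signature`
#'   (default: the xylan signature including CE1).
#' @param require_puf Additionally require at least one PUF member
#'   (default `FALSE`).
#' @param min_length,length_unit Minimal length of shortlisted PUFs;
#'   `min_length` in `length_unit` (`"aa"`, default, or `"bp"`, divided by 3
#'   on comparison). The default of 250 aa screens out fragments; set
#'   `min_length = NULL` to disable and report lengths as evidence only.
#' @return List of `candidate_report` objects for passing PULs only, each
#'   with `pul_id`, `substrate`, `flags`, and `shortlist` (data frame
#'   `locus_tag`, `signal_peptide`, `pfam`, `protein_length`).
#' @export
filter_candidates <- function(puls, min_proteins = 5, min_signature = 2,
                              signature_families =
                                default_signatures()$substrates$xylan$families,
                              require_puf = FALSE,
                              min_length = 250, length_unit = c("aa", "bp")) {
  length_unit <- match.arg(length_unit)
  if (inherits(puls, "pul")) puls <- list(puls)
  min_aa <- if (is.null(min_length)) 0
            else if (length_unit == "bp") min_length / 3 else min_length
  reports <- lapply(puls, function(p) {
    n_prot <- nrow(p$genes)
    n_sig <- sum(vapply(p$genes$labels, function(l)
      any(l %in% signature_families), logical(1)))
    is_puf <- vapply(p$genes$labels, function(l) "PUF" %in% l, logical(1))
    flags <- c(min_proteins = n_prot >= min_proteins,
               min_signature = n_sig >= min_signature,
               has_puf = !require_puf || any(is_puf))
    if (!all(flags)) return(NULL)
    sl <- p$genes[is_puf, , drop = FALSE]
    sl <- sl[sl$protein_length >= min_aa, , drop = FALSE]
    shortlist <- data.frame(
      locus_tag = sl$locus_tag,
      signal_peptide = if ("signal_peptide" %in% names(sl)) sl$signal_peptide
                       else NA,
      pfam = vapply(sl$pfam, function(pf) paste(pf, collapse = ","),
                    character(1)),
      protein_length = sl$protein_length,
      row.names = NULL)
    # signal-peptide-positive PUFs first (secretion evidence), longest next
    shortlist <- shortlist[order(!shortlist$signal_peptide,
                                 -shortlist$protein_length), , drop = FALSE]
    rownames(shortlist) <- NULL
    structure(list(pul_id = p$id, substrate = p$substrate,
                   n_proteins = n_prot, n_signature = n_sig,
                   flags = flags, shortlist = shortlist),
              class = "candidate_report")
  })
  Filter(Negate(is.null), reports)
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate report %s> substrate %s, %d proteins, %d signature CAZymes\n",
              x$pul_id, x$substrate, x$n_proteins, x$n_signature))
  if (nrow(x$shortlist)) {
    cat("  PUF shortlist:\n"); print(x$shortlist)
  } else cat("  no PUF members\n")
  invisible(x)
}

#' Group repeated PULs across samples
#'
#' Two loci are duplicates when their ordered member protein sequences are
#' identical, or when the shorter one equals a contiguous prefix (or suffix)
#' of the longer and is incomplete at the corresponding margin - the pattern
#' left by truncated assemblies of the same locus. Groups are transitive
#' closures of pairwise duplication; each group's representative is its
#' longest member.
#'
#' @param puls List of `pul` objects.
#' @param proteins Named character vector or `Biostrings::AAStringSet`
#'   mapping locus tags to protein sequences.
#' @return Data frame with one row per PUL: `pul_id`, `group`,
#'   `representative` (logical), `truncated` (matched as a truncated copy of
#'   a longer locus).
#' @export
deduplicate_puls <- function(puls, proteins) {
  if (inherits(proteins, "XStringSet")) {
    nm <- sub("\\s.*$", "", names(proteins))
    proteins <- setNames(as.character(proteins), nm)
  }
  tuples <- lapply(puls, function(p) {
    seqs <- proteins[p$genes$locus_tag]
    if (anyNA(seqs))
      stop("protein sequence missing for locus tag(s): ",
           paste(p$genes$locus_tag[is.na(seqs)], collapse = ", "))
    unname(seqs)
  })
  n <- length(puls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  truncated <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rel <- .dup_relation(puls[[i]], tuples[[i]], puls[[j]], tuples[[j]])
      if (rel$dup) {
        parent[find(j)] <- find(i)
        if (!is.na(rel$shorter)) truncated[c(i, j)[rel$shorter]] <- TRUE
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, unique(root))
  sizes <- vapply(puls, function(p) nrow(p$genes), integer(1))
  rep_flag <- rep(FALSE, n)
  for (g in unique(group)) {
    idx <- which(group == g)
    rep_flag[idx[which.max(sizes[idx])]] <- TRUE
  }
  data.frame(pul_id = vapply(puls, `[[`, character(1), "id"),
             group = group, representative = rep_flag, truncated = truncated,
             stringsAsFactors = FALSE)
}

# Pairwise duplicate relation; returns whether dup and which of (1, 2) is
# the truncated shorter copy (NA for exact equals).
.dup_relation <- function(p1, t1, p2, t2) {
  if (length(t1) == length(t2))
    return(list(dup = identical(t1, t2), shorter = NA_integer_))
  if (length(t1) < length(t2)) { s <- t1; l <- t2; sp <- p1; si <- 1L }
  else { s <- t2; l <- t1; sp <- p2; si <- 2L }
  k <- length(s)
  if (identical(s, l[seq_len(k)]) && !sp$complete_right)
    return(list(dup = TRUE, shorter = si))
  if (identical(s, l[(length(l) - k + 1):length(l)]) && !sp$complete_left)
    return(list(dup = TRUE, shorter = si))
  list(dup = FALSE, shorter = NA_integer_)
}

#' Summarize a list of PULs as a table
#'
#' @param puls List of `pul` objects.
#' @return Data frame: `pul_id`, `contig`, `start`, `end`, `n_genes`,
#'   `labels` (collapsed), `substrate`, `complete_left`, `complete_right`.
#' @export
pul_table <- function(puls) {
  if (!length(puls))
    return(data.frame(pul_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      n_genes = integer(0), labels = character(0),
                      substrate = character(0), complete_left = logical(0),
                      complete_right = logical(0)))
  do.call(rbind, lapply(puls, function(p) data.frame(
    pul_id = p$id, contig = p$contig,
    start = min(p$genes$start), end = max(p$genes$end),
    n_genes = nrow(p$genes),
    labels = paste(vapply(p$genes$labels, function(l)
      paste(l, collapse = "+"), character(1)), collapse = ";"),
    substrate = p$substrate,
    complete_left = p$complete_left, complete_right = p$complete_right,
    stringsAsFactors = FALSE)))
}
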