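# Seeded generators for desk-scale fixtures: annotated contigs carrying
# planted susC/susD-anchored gene clusters, before/after esterase spectra,
# and noisy initial-rate curves. Identical (seed, config) yields identical
# output; the planted truth is emitted alongside the fixture files.
#
# Protein sequences are random over the 20-letter alphabet with per-gene
# seeds derived from (fixture seed, gene index), and domain hits are emitted
# directly into the hit table: the HMM scanning that would produce them on
# real data is an upstream, external step.

.amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' A xylan-target PUL gene-label template
#'
#' Mirrors the anatomy of xylan-degrading loci: the susC/susD tandem pair
#' followed by xylan-acting glycoside hydrolases, a carbohydrate esterase,
#' and proteins of unknown function.
#'
#' @return Character vector of gene labels.
#' @export
xylan_pul_template <- function() {
  c("SUSC", "SUSD", "GH10", "GH43", "GH51", "CE1", "PUF", "PUF")
}

#' @rdname xylan_pul_template
#' @export
alginate_pul_template <- function() {
  c("SUSC", "SUSD", "PL6", "PL7", "PUF")
}

.template_ok <- function(labels) {
  known <- labels %in% c("SUSC", "SUSD", "PUF") |
    grepl(.cazy_label_pattern, labels)
  if (!all(known))
    stop("template references unknown label(s): ",
         paste(unique(labels[!known]), collapse = ", "))
  if (!any(labels == "SUSD"))
    stop("template must contain a SUSD gene (the detection anchor)")
  invisible(TRUE)
}

.protein_lengths <- c(SUSC = 900, SUSD = 520, PUF = 320, OTHER = 380)

.role_length <- function(label) {
  # deterministic length jitter comes from the main RNG stream
  base <- if (label %in% names(.protein_lengths)) .protein_lengths[[label]]
          else 450  # CAZy families
  base + sample(-60:60, 1)
}

.role_hits <- function(label, tag, candidate) {
  if (label == "SUSC")
    return(data.frame(locus_tag = tag, model = "SusC", e_value = 1e-80,
                      coverage = 0.95, ali_from = 20L, ali_to = 850L))
  if (label == "SUSD")
    return(data.frame(locus_tag = tag, model = "SusD", e_value = 1e-60,
                      coverage = 0.92, ali_from = 10L, ali_to = 480L))
  if (grepl(.cazy_label_pattern, label))
    return(data.frame(locus_tag = tag, model = paste0(label, ".hmm"),
                      e_value = 1e-30, coverage = 0.85, ali_from = 15L,
                      ali_to = 400L))
  if (label == "PUF" && candidate)
    return(data.frame(locus_tag = tag, model = "PF12695", e_value = 1e-12,
                      coverage = 0.60, ali_from = 30L, ali_to = 250L))
  if (label == "OTHER") {
    hk <- c("OmpA", "ABC_tran", "RpoB", "GyrA", "SecY", "DnaK")
    return(data.frame(locus_tag = tag, model = hk[1 + (sum(utf8ToInt(tag)) %% 6)],
                      e_value = 1e-25, coverage = 0.80, ali_from = 5L,
                      ali_to = 300L))
  }
  NULL  # plain PUF: no hits at all
}

#' Generate an annotated synthetic metagenome fixture with planted PULs
#'
#' Builds contigs of background genes (housekeeping functions) into which
#' PULs from the given label templates are planted, then writes the four
#' files the annotation module consumes - GFF3 gene models, protein FASTA,
#' domain-hit table, signal-peptide table - plus the planted truth as JSON.
#' Within a planted locus a geometric number of intervening background genes
#' (mean `gap_mean`, default 0: physically linked clusters) separates
#' consecutive template genes. With probability `margin_trunc_prob` a
#' planted locus is placed at the right contig margin with its tail
#' truncated, emulating incomplete assembly; the truth marks it incomplete.
#' The first PUF of each planted locus is the planted candidate: it carries
#' an alpha/beta-hydrolase Pfam domain (PF12695) and a signal peptide.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   files.
#' @param n_contigs Number of contigs.
#' @param n_puls Number of planted PULs (assigned to contigs round-robin).
#' @param templates List of label templates (recycled over planted PULs).
#' @param background_genes Background genes between/around planted loci is
#'   governed by `edge_pad` and `min_separation`; this sets the gene count
#'   of contigs that receive no PUL.
#' @param gap_mean Mean of the geometric count of intervening background
#'   genes between consecutive template genes (default 0).
#' @param margin_trunc_prob Probability that a planted PUL is truncated at
#'   the right contig margin.
#' @param min_separation Background genes between two planted loci on one
#'   contig (must exceed the detection gap tolerance for exact recovery).
#' @param edge_pad Background genes padding each contig end (idem).
#' @return Invisibly, a list with `files` (paths: `gff3`, `proteins`,
#'   `hits`, `signal`, `truth`) and `truth` (the `FixtureTruth` list:
#'   `seed`, `planted_puls`, `planted_candidates`).
#' @export
generate_metagenome <- function(out_dir, seed, n_contigs = 3, n_puls = 2,
                                templates = list(xylan_pul_template()),
                                background_genes = 8, gap_mean = 0,
                                margin_trunc_prob = 0, min_separation = 3,
                                edge_pad = 2) {
  lapply(templates, .template_ok)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  contigs <- sprintf("ctg%02d", seq_len(n_contigs))
  pul_contig <- contigs[1 + (seq_len(n_puls) - 1) %% n_contigs]
  pul_template <- templates[1 + (seq_len(n_puls) - 1) %% length(templates)]
  truncated <- runif(n_puls) < margin_trunc_prob

  # per-contig gene plans: data frame of (label, pul index or NA)
  plans <- list()
  truth_puls <- list()
  for (ctg in contigs) {
    mine <- which(pul_contig == ctg)
    # truncated loci must sit at the right margin: order them last
    mine <- mine[order(truncated[mine])]
    labs <- character(0); owner <- integer(0)
    add <- function(l, o) {
      labs <<- c(labs, l); owner <<- c(owner, rep(o, length(l)))
    }
    # only the last locus on a contig can sit at the right margin
    if (length(mine) > 1) truncated[mine[-length(mine)]] <- FALSE
    add(rep("OTHER", edge_pad), NA_integer_)
    if (!length(mine) && background_genes > edge_pad * 2)
      add(rep("OTHER", background_genes - edge_pad * 2), NA_integer_)
    for (p in mine) {
      tpl <- pul_template[[p]]
      if (truncated[p]) {
        susd_pos <- max(which(tpl == "SUSD"))
        droppable <- length(tpl) - susd_pos
        if (droppable >= 1) {
          k <- sample(seq_len(droppable), 1)
          tpl <- tpl[seq_len(length(tpl) - k)]
        } else truncated[p] <- FALSE
      }
      for (i in seq_along(tpl)) {
        add(tpl[i], p)
        if (i < length(tpl) && gap_mean > 0) {
          ng <- rgeom(1, 1 / (1 + gap_mean))
          if (ng > 0) add(rep("OTHER", ng), p)
        }
      }
      if (!truncated[p]) add(rep("OTHER", min_separation), NA_integer_)
    }
    last_trunc <- length(mine) && truncated[mine[length(mine)]]
    if (!last_trunc) add(rep("OTHER", max(0, edge_pad - min_separation *
                                            (length(mine) > 0))), NA_integer_)
    plans[[ctg]] <- data.frame(label = labs, pul = owner,
                               stringsAsFactors = FALSE)
  }

  # lay out genes: coordinates, lengths, strands, locus tags
  genes <- list(); gene_counter <- 0L
  for (ctg in contigs) {
    plan <- plans[[ctg]]
    pos <- sample(100:300, 1)
    strand_by_pul <- sample(c("+", "-"), n_puls, replace = TRUE)
    for (r in seq_len(nrow(plan))) {
      gene_counter <- gene_counter + 1L
      aa <- .role_length(plan$label[r])
      start <- pos
      end <- pos + 3L * (aa + 1L) - 1L
      pos <- end + sample(40:180, 1)
      genes[[gene_counter]] <- data.frame(
        contig = ctg, locus_tag = sprintf("%s_g%03d", ctg, r),
        start = start, end = end,
        strand = if (!is.na(plan$pul[r])) strand_by_pul[plan$pul[r]]
                 else sample(c("+", "-"), 1),
        label = plan$label[r], pul = plan$pul[r], aa = aa,
        gene_index = gene_counter, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)

  # candidates: first plain PUF of each planted locus
  genes$candidate <- FALSE
  for (p in seq_len(n_puls)) {
    pufs <- which(genes$pul == p & genes$label == "PUF")
    if (length(pufs)) {
      genes$candidate[pufs[1]] <- TRUE
      genes$aa[pufs[1]] <- max(genes$aa[pufs[1]], 260L)  # length-filter proof
      genes$end[pufs[1]] <- genes$start[pufs[1]] + 3L * (genes$aa[pufs[1]] + 1L) - 1L
    }
  }

  # truth
  for (p in seq_len(n_puls)) {
    rows <- genes[which(genes$pul == p), , drop = FALSE]
    truth_puls[[p]] <- list(
      contig = rows$contig[1],
      locus_tags = rows$locus_tag,
      labels = rows$label,
      span = c(min(rows$start) - 1L, max(rows$end)),  # 0-based half-open
      complete_left = TRUE,
      complete_right = !truncated[p])
  }
  truth <- list(seed = seed,
                planted_puls = truth_puls,
                planted_candidates = genes$locus_tag[genes$candidate])

  # protein sequences, per-gene seeds
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    set.seed((seed * 131L + genes$gene_index[i] * 7919L) %% 2147483647L)
    paste(sample(.amino_acids, genes$aa[i], replace = TRUE), collapse = "")
  }, character(1))

  # files
  paths <- list(gff3 = file.path(out_dir, "contigs.gff3"),
                proteins = file.path(out_dir, "proteins.faa"),
                hits = file.path(out_dir, "domain_hits.tsv"),
                signal = file.path(out_dir, "signal_peptides.tsv"),
                truth = file.path(out_dir, "truth.json"))
  ctg_len <- tapply(genes$end, genes$contig, max) + 50L
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(ctg_len),
                                    seqlengths = as.integer(ctg_len)))
  S4Vectors::mcols(gr)$source <- "pulminer_synth"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- genes$locus_tag
  rtracklayer::export(gr, paths$gff3, format = "gff3")
  # add sequence-region pragmas (contig bounds) after the version line
  gff_lines <- readLines(paths$gff3)
  ver <- grep("^##gff-version", gff_lines)[1]
  pragmas <- sprintf("##sequence-region %s 1 %d", names(ctg_len),
                     as.integer(ctg_len))
  writeLines(append(gff_lines, pragmas, after = ver), paths$gff3)

  aa_set <- Biostrings::AAStringSet(setNames(seqs, genes$locus_tag))
  Biostrings::writeXStringSet(aa_set, paths$proteins)

  hits <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    .role_hits(genes$label[i], genes$locus_tag[i], genes$candidate[i])))
  write.table(hits, paths$hits, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  signal <- data.frame(locus_tag = genes$locus_tag,
                       signal = as.integer(genes$candidate |
                                             genes$label == "SUSD"))
  write.table(signal, paths$signal, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(files = paths, truth = truth))
}

#' Generate a before/after MALDI-TOF peak-list pair for an esterase reaction
#'
#' Before-peaks are the adduct masses of the substrate compositions; the
#' after-spectrum replaces each substrate by its reaction product(s), with
#' optional uniform m/z jitter emulating calibration error. Jitter must stay
#' below the matching tolerance used downstream.
#'
#' @param substrates List of [glycan_composition()] objects.
#' @param remove_ac,remove_fa Groups hydrolysed per substrate: a count or
#'   `"all"`. A count exceeding a substrate's content is an error.
#' @param mz_jitter Half-width (Da) of uniform jitter on every peak.
#' @param seed Integer seed.
#' @param adduct Reported adduct.
#' @return List with `before` and `after` peak data frames (`mz`,
#'   `intensity`) and `products` (the product compositions).
#' @export
generate_spectrum_pair <- function(substrates, remove_ac = 0, remove_fa = 0,
                                   mz_jitter = 0, seed = 1,
                                   adduct = c("Na", "H", "none")) {
  adduct <- match.arg(adduct)
  if (inherits(substrates, "glycan_composition")) substrates <- list(substrates)
  set.seed(seed)
  subs <- lapply(substrates, .as_composition)
  products <- lapply(subs, function(s) {
    ka <- if (identical(remove_ac, "all")) s[["Ac"]] else remove_ac
    kf <- if (identical(remove_fa, "all")) s[["Fa"]] else remove_fa
    predict_products(s, remove_ac = ka, remove_fa = kf, adduct = adduct)$product
  })
  jitter <- function(n) if (mz_jitter > 0) runif(n, -mz_jitter, mz_jitter)
                        else rep(0, n)
  b_mass <- vapply(subs, composition_mass, numeric(1), adduct = adduct)
  a_mass <- unique(vapply(products, composition_mass, numeric(1),
                          adduct = adduct))
  before <- data.frame(mz = b_mass + jitter(length(b_mass)),
                       intensity = round(runif(length(b_mass), 0.3, 1), 3))
  after <- data.frame(mz = a_mass + jitter(length(a_mass)),
                      intensity = round(runif(length(a_mass), 0.3, 1), 3))
  list(before = before, after = after, products = products)
}

#' Generate an initial-rate table under substrate inhibition
#'
#' Rates follow [rate_si()] with optional multiplicative Gaussian noise of
#' relative standard deviation `noise` (rates are clamped at zero). With
#' `noise = 0` the returned rates equal the model curve exactly.
#'
#' @param model An [si_model()].
#' @param S Substrate concentration grid (mM, positive).
#' @param noise Relative noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `S` (mM) and `v0`.
#' @export
generate_kinetics <- function(model, S = seq(0.25, 10, length.out = 40),
                              noise = 0, seed = NULL) {
  stopifnot(inherits(model, "si_model"))
  if (any(S <= 0)) stop("S grid must be positive")
  if (noise < 0) stop("noise must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  v <- rate_si(S, model$Vmax, model$Km, model$Ki)
  v0 <- if (noise > 0) pmax(0, v * (1 + rnorm(length(S), 0, noise))) else v
  data.frame(S = S, v0 = v0)
}
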