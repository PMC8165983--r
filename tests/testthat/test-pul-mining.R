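test_that("a contiguous susD-anchored cluster is detected whole", {
  f <- make_features(c("SUSC", "SUSD", "GH10", "GH43", "PUF"))
  puls <- detect_puls(f, max_gap = 0)
  expect_length(puls, 1)
  expect_equal(nrow(puls[[1]]$genes), 5)
  # the locus spans the whole contig: open at both assembly margins
  expect_false(puls[[1]]$complete_left)
  expect_false(puls[[1]]$complete_right)
})

test_that("CAZymes without a susD anchor never form a locus", {
  f <- make_features(c("GH10", "GH43", "CE1", "SUSC"))
  expect_length(detect_puls(f), 0)
})

test_that("gap tolerance governs extension through unrelated genes", {
  f <- make_features(c("SUSD", "GH10", "OTHER", "OTHER", "GH43"))
  p1 <- detect_puls(f, max_gap = 1)
  expect_equal(p1[[1]]$genes$locus_tag, c("c1_g01", "c1_g02"))
  p2 <- detect_puls(f, max_gap = 2)
  expect_equal(nrow(p2[[1]]$genes), 5)
  # matches the brute-force enumeration in both cases
  memb <- vapply(f$labels, is_extendable_label, logical(1))
  susd <- vapply(f$labels, function(l) "SUSD" %in% l, logical(1))
  expect_equal(lapply(p1, function(p) range(match(p$genes$locus_tag, f$locus_tag))),
               lapply(oracle_clusters(memb, susd, 1), as.integer))
  expect_equal(lapply(p2, function(p) range(match(p$genes$locus_tag, f$locus_tag))),
               lapply(oracle_clusters(memb, susd, 2), as.integer))
})

test_that("require_susc drops loci lacking the transporter", {
  f <- make_features(c("SUSD", "GH10", "GH43"))
  expect_length(detect_puls(f, require_susc = FALSE), 1)
  expect_length(detect_puls(f, require_susc = TRUE), 0)
})

test_that("completeness flags reflect proximity to contig margins", {
  f <- make_features(c("SUSD", "GH10", "OTHER", "OTHER", "OTHER"))
  p <- detect_puls(f, max_gap = 1)[[1]]
  expect_false(p$complete_left)   # locus starts at the first gene
  expect_true(p$complete_right)   # 3 non-members follow, more than the gap
  f2 <- make_features(c("OTHER", "OTHER", "GH43", "SUSD"))
  p2 <- detect_puls(f2, max_gap = 1)[[1]]
  expect_true(p2$complete_left)
  expect_false(p2$complete_right)
})

test_that("increasing the gap tolerance never shrinks or splits a locus", {
  set.seed(101)
  pool <- c("SUSD", "SUSC", "GH10", "GH43", "CE1", "PUF", "OTHER", "OTHER")
  for (trial in 1:50) {
    f <- make_features(sample(pool, sample(5:14, 1), replace = TRUE))
    prev <- NULL
    for (g in 0:3) {
      puls <- detect_puls(f, max_gap = g)
      sizes <- vapply(puls, function(p) nrow(p$genes), integer(1))
      if (!is.null(prev)) {
        expect_lte(length(puls), length(prev$n))  # merging only
        # every earlier locus is contained in some locus at larger g
        for (w in prev$win) {
          containing <- vapply(puls, function(p) {
            r <- range(match(p$genes$locus_tag, f$locus_tag))
            r[1] <= w[1] && w[2] <= r[2]
          }, logical(1))
          expect_true(any(containing))
        }
      }
      prev <- list(n = sizes, win = lapply(puls, function(p)
        range(match(p$genes$locus_tag, f$locus_tag))))
    }
  }
})

test_that("substrate inference follows signatures, ties, and evidence counts", {
  f <- make_features(c("SUSD", "GH10", "GH43", "PUF"))
  p <- infer_substrate(detect_puls(f)[[1]])
  expect_equal(p$substrate, "xylan")
  expect_setequal(p$evidence$family, c("GH10", "GH43"))
  # only CBMs: no signature met
  f2 <- make_features(c("SUSD", "CBM6", "CBM13"))
  expect_equal(infer_substrate(detect_puls(f2)[[1]])$substrate, "unknown")
  # two distinct alginate-lyase families force the alginate call
  f3 <- make_features(c("SUSD", "PL6", "PL7"))
  expect_equal(infer_substrate(detect_puls(f3)[[1]])$substrate, "alginate")
  # one signature family is not enough (minimum two distinct)
  f4 <- make_features(c("SUSD", "GH10", "GH10"))
  expect_equal(infer_substrate(detect_puls(f4)[[1]])$substrate, "unknown")
  # overlapping signatures without a priority order are a config error
  bad <- list(substrates = list(a = list(families = "GH10", min_families = 1),
                                b = list(families = "GH10", min_families = 1)),
              priority = NULL)
  expect_error(infer_substrate(detect_puls(f4)[[1]], signatures = bad),
               "priority")
})

test_that("candidate filtering applies the protein and signature minima", {
  f5 <- make_features(c("SUSC", "SUSD", "GH10", "GH43", "PUF"))
  p5 <- infer_substrate(detect_puls(f5))
  rep5 <- filter_candidates(p5, min_proteins = 5, min_signature = 2)
  expect_length(rep5, 1)
  expect_equal(nrow(rep5[[1]]$shortlist), 1)
  expect_false(rep5[[1]]$shortlist$signal_peptide[1])  # listed, flag false
  # one protein fewer fails the minimum
  f4 <- make_features(c("SUSD", "GH10", "GH43", "PUF"))
  expect_length(filter_candidates(infer_substrate(detect_puls(f4)),
                                  min_proteins = 5, min_signature = 2), 0)
  # signature requirement
  f5b <- make_features(c("SUSC", "SUSD", "GH10", "PUF", "PUF"))
  expect_length(filter_candidates(infer_substrate(detect_puls(f5b)),
                                  min_proteins = 5, min_signature = 2), 0)
})

test_that("duplicate grouping handles identical and margin-truncated loci", {
  seqs_full <- c("MAAA", "MBBB", "MCCC", "MDDD", "MEEE", "MFFF", "MGGG")
  p1 <- make_pul("p1", seqs_full)
  p2 <- make_pul("p2", seqs_full)                       # identical copy
  p3 <- make_pul("p3", seqs_full[1:5], complete_right = FALSE)  # truncated prefix
  p4 <- make_pul("p4", seqs_full[1:4])                  # complete prefix copy
  p5 <- make_pul("p5", c(seqs_full[1:4], "MXXX"))       # one substitution
  prots <- pul_proteins(list(p1, p2, p3, p4, p5),
                        list(seqs_full, seqs_full, seqs_full[1:5],
                             seqs_full[1:4], c(seqs_full[1:4], "MXXX")))
  dd <- deduplicate_puls(list(p1, p2, p3, p4, p5), prots)
  grp <- function(id) dd$group[dd$pul_id == id]
  expect_equal(grp("p1"), grp("p2"))
  expect_equal(grp("p1"), grp("p3"))   # truncated prefix joins the group
  expect_false(grp("p4") == grp("p1")) # complete shorter copy does not
  expect_false(grp("p5") == grp("p1")) # substitution separates
  expect_true(dd$truncated[dd$pul_id == "p3"])
  expect_true(dd$representative[dd$pul_id == "p1"] ||
                dd$representative[dd$pul_id == "p2"])
  # suffix-truncated copy incomplete on the left also joins
  p6 <- make_pul("p6", seqs_full[3:7], complete_left = FALSE)
  prots2 <- c(prots, setNames(seqs_full[3:7], p6$genes$locus_tag))
  dd2 <- deduplicate_puls(list(p1, p6), prots2)
  expect_equal(dd2$group[1], dd2$group[2])
})

test_that("duplicate grouping matches the brute-force comparer and is order-invariant", {
  set.seed(77)
  alphabet <- c("MAAA", "MBBB", "MCCC", "MDDD", "MEEE")
  for (trial in 1:40) {
    n <- sample(2:6, 1)
    puls <- list(); seq_lists <- list()
    for (i in seq_len(n)) {
      len <- sample(2:5, 1)
      seqs <- sample(alphabet, len, replace = TRUE)
      puls[[i]] <- make_pul(paste0("q", i), seqs,
                            complete_left = runif(1) > 0.3,
                            complete_right = runif(1) > 0.3)
      seq_lists[[i]] <- seqs
    }
    prots <- pul_proteins(puls, seq_lists)
    dd <- deduplicate_puls(puls, prots)
    got <- partition_of(dd$pul_id, dd$group)
    want <- lapply(oracle_dedup(puls, prots), function(idx)
      sort(vapply(puls[idx], `[[`, character(1), "id")))
    want <- want[order(vapply(want, `[`, character(1), 1))]
    expect_equal(got, want)
    # idempotence on representatives and permutation invariance
    perm <- sample(n)
    dd_p <- deduplicate_puls(puls[perm], prots)
    expect_equal(partition_of(dd_p$pul_id, dd_p$group), got)
  }
})

test_that("planted loci are recovered exactly across seeds", {
  for (seed in 1:20) {
    fx <- generate_metagenome(withr::local_tempdir(), seed = seed,
                              n_contigs = 3, n_puls = 3,
                              margin_trunc_prob = ifelse(seed %% 2, 0, 0.5))
    feats <- load_features(fx$files$gff3, fx$files$proteins)
    lab <- assign_labels(feats, load_domain_hits(fx$files$hits),
                         read_signal_table(fx$files$signal))
    puls <- detect_puls(lab, max_gap = 1)
    planted <- lapply(fx$truth$planted_puls, `[[`, "locus_tags")
    detected <- lapply(puls, function(p) p$genes$locus_tag)
    # sensitivity = precision = 1: the two sets of tag vectors coincide
    key <- function(x) vapply(x, paste, character(1), collapse = "|")
    expect_setequal(key(detected), key(planted))
    # completeness flags agree with the planted truth
    for (i in seq_along(planted)) {
      truth_pul <- fx$truth$planted_puls[[i]]
      det <- puls[[match(key(planted)[i], key(detected))]]
      expect_equal(det$complete_right, truth_pul$complete_right)
      expect_equal(det$complete_left, truth_pul$complete_left)
    }
  }
})
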