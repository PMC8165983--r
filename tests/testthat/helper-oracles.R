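# Fixture builders and independent brute-force oracles used across tests.

# ---- feature/PUL builders -------------------------------------------------

# labelled feature table from a plain label vector (one gene per label)
make_features <- function(labels, contig = "c1") {
  n <- length(labels)
  df <- data.frame(contig = contig,
                   locus_tag = sprintf("%s_g%02d", contig, seq_len(n)),
                   start = seq(0L, by = 1000L, length.out = n),
                   end = seq(900L, by = 1000L, length.out = n),
                   strand = "+",
                   protein_length = 300L,
                   stringsAsFactors = FALSE)
  df$labels <- lapply(labels, identity)
  df$pfam <- rep(list(character(0)), n)
  df$signal_peptide <- FALSE
  class(df) <- c("gene_features", "data.frame")
  df
}

# minimal pul object over given protein sequences (for deduplication tests)
make_pul <- function(id, seqs, complete_left = TRUE, complete_right = TRUE) {
  tags <- paste0(id, "_m", seq_along(seqs))
  genes <- data.frame(contig = id, locus_tag = tags,
                      start = seq_along(seqs) * 100L,
                      end = seq_along(seqs) * 100L + 50L,
                      strand = "+", protein_length = nchar(seqs),
                      stringsAsFactors = FALSE)
  genes$labels <- rep(list("PUF"), length(seqs))
  structure(list(id = id, contig = id, genes = genes,
                 anchors = list(susd = 1L, susc = integer(0)),
                 complete_left = complete_left,
                 complete_right = complete_right,
                 substrate = NA_character_, evidence = NULL),
            class = "pul")
}

# named protein vector for a list of make_pul() objects
pul_proteins <- function(puls, seq_lists) {
  out <- character(0)
  for (i in seq_along(puls))
    out <- c(out, setNames(seq_lists[[i]], puls[[i]]$genes$locus_tag))
  out
}

# ---- brute-force PUL cluster enumerator -----------------------------------

# all maximal contiguous windows that start/end on member genes, contain a
# SUSD gene, and have no run of more than g consecutive non-member genes
oracle_clusters <- function(memb, susd, g) {
  n <- length(memb)
  valid <- list()
  for (a in seq_len(n)) for (b in a:n) {
    if (!memb[a] || !memb[b]) next
    if (!any(susd[a:b])) next
    runs <- rle(memb[a:b])
    if (any(!runs$values & runs$lengths > g)) next
    valid[[length(valid) + 1L]] <- c(a, b)
  }
  if (!length(valid)) return(list())
  keep <- vapply(seq_along(valid), function(i) {
    w <- valid[[i]]
    !any(vapply(valid, function(v)
      v[1] <= w[1] && w[2] <= v[2] && !(v[1] == w[1] && v[2] == w[2]),
      logical(1)))
  }, logical(1))
  unique(valid[keep])
}

# ---- brute-force PUL duplicate grouping -----------------------------------

oracle_dedup <- function(puls, proteins) {
  tuples <- lapply(puls, function(p) unname(proteins[p$genes$locus_tag]))
  dup <- function(i, j) {
    a <- tuples[[i]]; b <- tuples[[j]]
    if (length(a) == length(b)) return(identical(a, b))
    if (length(a) < length(b)) { s <- a; l <- b; sp <- puls[[i]] }
    else { s <- b; l <- a; sp <- puls[[j]] }
    k <- length(s)
    (identical(s, l[seq_len(k)]) && !sp$complete_right) ||
      (identical(s, l[(length(l) - k + 1):length(l)]) && !sp$complete_left)
  }
  n <- length(puls)
  adj <- diag(TRUE, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <- dup(i, j)
  # transitive closure
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  groups <- unique(lapply(seq_len(n), function(i) sort(which(adj[i, ] > 0))))
  groups
}

# canonical partition form for comparing groupings
partition_of <- function(ids, group) {
  sets <- unname(split(ids, group))
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# ---- exhaustive composition enumeration (glyco oracle) --------------------

# independent nested-loop lattice enumeration; returns composition keys
oracle_compositions <- function(bounds = c(P = 8, H = 3, Ac = 8, Fa = 4, U = 2),
                                adduct_mass = 22.9892, water = 18.0106) {
  rm <- c(P = 132.0423, H = 162.0528, Ac = 42.0106, Fa = 176.0473,
          U = 190.0477)
  out <- list(); i <- 0L
  for (P in 0:bounds["P"]) for (H in 0:bounds["H"])
    for (Ac in 0:bounds["Ac"]) for (Fa in 0:bounds["Fa"])
      for (U in 0:bounds["U"]) {
        if (P + H < 1) next
        i <- i + 1L
        out[[i]] <- c(P = P, H = H, Ac = Ac, Fa = Fa, U = U,
                      mass = P * rm["P"] + H * rm["H"] + Ac * rm["Ac"] +
                        Fa * rm["Fa"] + U * rm["U"] + water + adduct_mass)
      }
  m <- do.call(rbind, out)
  data.frame(key = sprintf("P%dH%dAc%dFa%dU%d", m[, 1], m[, 2], m[, 3],
                           m[, 4], m[, 5]),
             mass = m[, 6], stringsAsFactors = FALSE)
}

comp_keys <- function(matches) {
  sprintf("P%dH%dAc%dFa%dU%d", matches$P, matches$H, matches$Ac,
          matches$Fa, matches$U)
}

# ---- exhaustive clade scan (phylogeny oracle) -----------------------------

# tip labels under a node, walking tree$edge directly
oracle_desc_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  tips <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    if (nd <= ntip) tips <- c(tips, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
  }
  tree$tip.label[tips]
}

# smallest clade (over every node of the tree) containing all target tips
oracle_clade <- function(tree, cls, target) {
  ntip <- length(tree$tip.label)
  targets <- tree$tip.label[cls[tree$tip.label] == target]
  nodes <- seq_len(ntip + tree$Nnode)
  sets <- lapply(nodes, function(nd) oracle_desc_tips(tree, nd))
  containing <- Filter(function(s) all(targets %in% s), sets)
  best <- containing[[which.min(lengths(containing))]]
  list(mono = all(cls[best] == target), clade = sort(best))
}
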