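# Residue-composition mass arithmetic and MALDI-TOF peak annotation for
# substituted xylooligosaccharides.
#
# Masses are monoisotopic residue masses (monomer minus water); a neutral
# oligosaccharide mass is the residue sum plus one water, and the reported
# m/z adds the adduct mass. Electron mass is ignored (<< the 0.1 Da precision
# at which MALDI-TOF peaks are read).

#' Monoisotopic residue and adduct masses (Da)
#'
#' Residue symbols follow the convention for substituted xylan fragments:
#' `P` pentose (xylosyl/arabinosyl), `H` hexose (e.g. galactosyl), `Ac`
#' acetyl, `Fa` feruloyl, `U` (4-O-methyl)glucuronyl.
#'
#' @format Named numeric vector of residue masses in Da.
#' @export
RESIDUE_MASSES <- c(
  P  = 132.0423,
  H  = 162.0528,
  Ac = 42.0106,
  Fa = 176.0473,
  U  = 190.0477
)

#' @rdname RESIDUE_MASSES
#' @export
WATER_MASS <- 18.0106

ADDUCT_MASSES <- c(Na = 22.9892, H = 1.0073, none = 0)

.composition_symbols <- names(RESIDUE_MASSES)

#' Construct a glycan residue composition
#'
#' @param P,H,Ac,Fa,U Non-negative integer counts of pentose, hexose, acetyl,
#'   feruloyl and (4-O-methyl)glucuronyl residues.
#' @return A `glycan_composition`: a named integer vector over the five
#'   residue symbols.
#' @examples
#' glycan_composition(P = 5, Fa = 1, Ac = 1)
#' @export
glycan_composition <- function(P = 0, H = 0, Ac = 0, Fa = 0, U = 0) {
  x <- c(P = P, H = H, Ac = Ac, Fa = Fa, U = U)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("composition counts must be non-negative integers")
  structure(as.integer(x), names = .composition_symbols,
            class = "glycan_composition")
}

.as_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    unknown <- setdiff(names(x), .composition_symbols)
    if (length(unknown))
      stop("unknown residue symbol(s): ", paste(unknown, collapse = ", "))
    full <- setNames(integer(length(.composition_symbols)), .composition_symbols)
    full[names(x)] <- as.integer(x)
    return(do.call(glycan_composition, as.list(full)))
  }
  stop("cannot interpret object as a glycan composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) return("(empty)")
  paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format(x), "  neutral mass ",
      sprintf("%.4f", composition_mass(x, adduct = "none")), " Da\n", sep = "")
  invisible(x)
}

#' Mass of a residue composition under an ionization adduct
#'
#' Computes `sum(counts * residue mass) + water + adduct mass`. MALDI-TOF
#' spectra of neutral oligosaccharides are conventionally read as sodium
#' adducts, the default here.
#'
#' @param composition A [glycan_composition()] or named count vector.
#' @param adduct One of `"Na"`, `"H"`, `"none"`.
#' @return m/z (equivalently the neutral mass for `adduct = "none"`), in Da.
#' @examples
#' composition_mass(glycan_composition(P = 5, Fa = 1, Ac = 1))  # 919.27
#' @export
composition_mass <- function(composition, adduct = c("Na", "H", "none")) {
  adduct <- match.arg(adduct)
  comp <- .as_composition(composition)
  sum(as.numeric(comp) * RESIDUE_MASSES) + WATER_MASS + ADDUCT_MASSES[[adduct]]
}

.feasible <- function(P, H, Ac, Fa, U) {
  # Ester groups occupy sugar hydroxyls; feruloyl rides an arabinofuranosyl
  # (pentose) carrier.
  (Ac + Fa) <= 2 * (P + H) & Fa <= P
}

#' Annotate one m/z peak with candidate residue compositions
#'
#' Enumerates every composition within `bounds` whose adduct mass falls
#' within `tolerance` of the observed m/z, requiring at least one sugar
#' residue (P + H >= 1). With `feasibility = TRUE` compositions violating the
#' ester-capacity rules (Ac + Fa <= 2(P + H), Fa <= P) are excluded; with
#' `feasibility = FALSE` they are retained and flagged. Matches are ranked by
#' |delta m/z|, ties broken by fewer total substituents (Ac + Fa + U), then
#' lexicographically on (P, H, Ac, Fa, U).
#'
#' @param mz Observed m/z (Da).
#' @param tolerance Matching tolerance in Da (> 0).
#' @param bounds Named vector of maximal counts per residue symbol.
#' @param feasibility Apply ester-capacity rules as a hard filter?
#' @param adduct Adduct assumed for all candidate compositions.
#' @return A `peak_annotation`: list with `mz`, `tolerance`, `adduct` and a
#'   `matches` data frame (`P, H, Ac, Fa, U, mass, delta, feasible`).
#' @examples
#' decompose_peak(919.3, tolerance = 0.3)
#' @export
decompose_peak <- function(mz, tolerance = 0.3,
                           bounds = c(P = 8, H = 3, Ac = 8, Fa = 4, U = 2),
                           feasibility = TRUE,
                           adduct = c("Na", "H", "none")) {
  adduct <- match.arg(adduct)
  if (!is.numeric(tolerance) || tolerance < 0)
    stop("tolerance must be a non-negative number")
  full <- setNames(integer(length(.composition_symbols)), .composition_symbols)
  unknown <- setdiff(names(bounds), .composition_symbols)
  if (length(unknown))
    stop("unknown residue symbol(s) in bounds: ", paste(unknown, collapse = ", "))
  full[names(bounds)] <- as.integer(bounds)
  grid <- expand.grid(P = 0:full["P"], H = 0:full["H"], Ac = 0:full["Ac"],
                      Fa = 0:full["Fa"], U = 0:full["U"])
  grid <- grid[grid$P + grid$H >= 1L, , drop = FALSE]
  mass <- as.matrix(grid) %*% RESIDUE_MASSES[.composition_symbols] +
    WATER_MASS + ADDUCT_MASSES[[adduct]]
  grid$mass <- as.numeric(mass)
  grid$delta <- grid$mass - mz
  grid <- grid[abs(grid$delta) <= tolerance, , drop = FALSE]
  grid$feasible <- .feasible(grid$P, grid$H, grid$Ac, grid$Fa, grid$U)
  if (feasibility) grid <- grid[grid$feasible, , drop = FALSE]
  key <- sprintf("%03d%03d%03d%03d%03d", grid$P, grid$H, grid$Ac, grid$Fa, grid$U)
  grid <- grid[order(abs(grid$delta), grid$Ac + grid$Fa + grid$U, key), ,
               drop = FALSE]
  rownames(grid) <- NULL
  structure(list(mz = mz, tolerance = tolerance, adduct = adduct,
                 matches = grid),
            class = "peak_annotation")
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("<peak annotation> m/z %.4f (+-%.2f Da, %s adduct): %d match(es)\n",
              x$mz, x$tolerance, x$adduct, nrow(x$matches)))
  if (nrow(x$matches)) print(utils::head(x$matches, 10))
  invisible(x)
}

#' Predict esterase reaction products of a substituted oligosaccharide
#'
#' Ester hydrolysis releases the acyl group as the free acid (water goes to
#' the acid), so the sugar product loses exactly the acyl residue mass per
#' removed group: 42.0106 Da per acetyl, 176.0473 Da per feruloyl.
#'
#' @param composition Substrate [glycan_composition()].
#' @param remove_ac,remove_fa Number of acetyl / feruloyl groups hydrolysed.
#'   Must not exceed the substrate counts.
#' @param adduct Adduct for the reported product m/z.
#' @return List with `product` (a `glycan_composition`) and `mass` (product
#'   adduct m/z).
#' @examples
#' predict_products(glycan_composition(P = 2, Ac = 5), remove_ac = 1)
#' @export
predict_products <- function(composition, remove_ac = 0, remove_fa = 0,
                             adduct = c("Na", "H", "none")) {
  adduct <- match.arg(adduct)
  comp <- .as_composition(composition)
  if (remove_ac < 0 || remove_fa < 0)
    stop("numbers of removed groups must be non-negative")
  if (remove_ac > comp[["Ac"]])
    stop("cannot remove ", remove_ac, " acetyl group(s): substrate carries ",
         comp[["Ac"]])
  if (remove_fa > comp[["Fa"]])
    stop("cannot remove ", remove_fa, " feruloyl group(s): substrate carries ",
         comp[["Fa"]])
  prod <- comp
  prod[["Ac"]] <- prod[["Ac"]] - as.integer(remove_ac)
  prod[["Fa"]] <- prod[["Fa"]] - as.integer(remove_fa)
  prod <- do.call(glycan_composition, as.list(setNames(as.integer(prod),
                                                       names(prod))))
  list(product = prod, mass = composition_mass(prod, adduct = adduct))
}

#' Infer released moieties from before/after MALDI-TOF peak lists
#'
#' For each peak of the "before" (substrate) spectrum, searches the "after"
#' (product) spectrum at masses shifted by `-k * 42.0106` (acetyl) and/or
#' `-j * 176.0473` (feruloyl) Da, `0 <= k <= max_ac`, `0 <= j <= max_fa`.
#' Every consistent `(k, j)` shift is reported; the minimal explanation per
#' peak (fewest removed groups, then smallest |delta|) drives the summary, so
#' an unshifted match is reported as "no change".
#'
#' @param before,after Peak lists: numeric m/z vectors, or data frames whose
#'   first column is m/z (intensities are carried but not used).
#' @param tolerance Matching tolerance in Da.
#' @param max_ac,max_fa Maximal numbers of removed acetyl/feruloyl groups
#'   considered per peak.
#' @return A `spectrum_comparison`: list with `per_peak` (minimal explanation
#'   per before-peak; `NA` shifts mean unexplained), `all_matches` (every
#'   consistent shift) and `summary` (logical `acetyl_released`,
#'   `feruloyl_released`, `unchanged`).
#' @export
compare_spectra <- function(before, after, tolerance = 0.3,
                            max_ac = 6, max_fa = 3) {
  bmz <- .peak_mz(before)
  amz <- .peak_mz(after)
  shifts <- expand.grid(k = 0:max_ac, j = 0:max_fa)
  all <- do.call(rbind, lapply(seq_along(bmz), function(i) {
    expected <- bmz[i] - shifts$k * RESIDUE_MASSES[["Ac"]] -
      shifts$j * RESIDUE_MASSES[["Fa"]]
    hit <- vapply(expected, function(m) {
      d <- amz - m
      ok <- abs(d) <= tolerance
      if (any(ok)) which.min(abs(d)) else NA_integer_
    }, integer(1))
    keep <- !is.na(hit)
    if (!any(keep)) return(NULL)
    data.frame(before_mz = bmz[i], n_ac_removed = shifts$k[keep],
               n_fa_removed = shifts$j[keep], after_mz = amz[hit[keep]],
               delta = amz[hit[keep]] - expected[keep])
  }))
  if (is.null(all))
    all <- data.frame(before_mz = numeric(0), n_ac_removed = integer(0),
                      n_fa_removed = integer(0), after_mz = numeric(0),
                      delta = numeric(0))
  per_peak <- do.call(rbind, lapply(bmz, function(b) {
    sub <- all[all$before_mz == b, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(before_mz = b, n_ac_removed = NA_integer_,
                        n_fa_removed = NA_integer_, after_mz = NA_real_,
                        delta = NA_real_))
    sub[order(sub$n_ac_removed + sub$n_fa_removed, abs(sub$delta)), ,
        drop = FALSE][1, , drop = FALSE]
  }))
  rownames(per_peak) <- NULL
  explained <- !is.na(per_peak$n_ac_removed)
  summary <- list(
    acetyl_released = any(per_peak$n_ac_removed[explained] > 0),
    feruloyl_released = any(per_peak$n_fa_removed[explained] > 0),
    unchanged = all(explained) && all(per_peak$n_ac_removed == 0) &&
      all(per_peak$n_fa_removed == 0)
  )
  structure(list(per_peak = per_peak, all_matches = all, summary = summary,
                 tolerance = tolerance),
            class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  s <- x$summary
  cat("<spectrum comparison>\n")
  if (s$unchanged) {
    cat("  no change: every substrate peak matched unshifted\n")
  } else {
    cat("  acetyl released:  ", s$acetyl_released, "\n",
        "  feruloyl released:", s$feruloyl_released, "\n", sep = " ")
  }
  print(x$per_peak)
  invisible(x)
}

.peak_mz <- function(x) {
  if (is.data.frame(x)) x <- x[[1]]
  if (!is.numeric(x) || !length(x)) stop("peak list must contain numeric m/z")
  as.numeric(x)
}

#' Read / write a two-column (m/z, intensity) peak list
#'
#' Plain whitespace-separated text, the common export of MALDI-TOF
#' processing software. A single m/z column is accepted on read (intensity
#' defaults to 1).
#'
#' @param path File path.
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @return `read_peaklist` returns a data frame with `mz` and `intensity`.
#' @export
read_peaklist <- function(path) {
  tab <- read.table(path, header = FALSE, col.names = c("mz", "intensity")[
    seq_len(max(count.fields(path)))])
  if (is.null(tab$intensity)) tab$intensity <- 1
  tab
}

#' @rdname read_peaklist
#' @export
write_peaklist <- function(peaks, path) {
  write.table(peaks[, c("mz", "intensity")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
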