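# Downstream analyses: quartet categorization (single vs. independent
# duplication, WGD annotation), asymmetry summaries, subcellular
# localization configurations, and mapping the recurrent signal back onto
# alignment columns.

#' Categorize quartets by duplication history
#'
#' A quartet is an independent-duplication quartet when its two species lie
#' in different duplication blocks.  Single-duplication quartets are
#' subdivided into whole-genome-duplication (WGD) quartets — at least one of
#' the two pairs carries a WGD annotation — and Other quartets.
#'
#' @param qtab Quartet table.
#' @param dups Duplication clustering from [cluster_editing()].
#' @param wgd Optional WGD annotation table: data frame with columns
#'   `species`, `gene_a`, `gene_b`, `label` (label `"WGD"` marks an ohnolog
#'   pair; any other label marks an explicitly non-WGD pair).
#' @return `qtab` with added columns `category` (one of
#'   `independent_duplication`, `single_duplication_wgd`,
#'   `single_duplication_other`, or `NA` for conflicting annotations) and
#'   `category_flagged`.
#' @export
categorize_quartets <- function(qtab, dups, wgd = NULL) {
  bx <- dups$membership[qtab$species_x]
  by <- dups$membership[qtab$species_y]
  lookup <- function(sp, ga, gb) {
    if (is.null(wgd)) return(NA_character_)
    hit <- wgd$species == sp &
      ((wgd$gene_a == ga & wgd$gene_b == gb) |
         (wgd$gene_a == gb & wgd$gene_b == ga))
    if (!any(hit)) NA_character_ else wgd$label[which(hit)[1L]]
  }
  cat_out <- character(nrow(qtab))
  flag <- logical(nrow(qtab))
  for (k in seq_len(nrow(qtab))) {
    if (is.na(bx[k]) || is.na(by[k]) || bx[k] != by[k]) {
      cat_out[k] <- "independent_duplication"
      next
    }
    l1 <- lookup(qtab$species_x[k], qtab$gene_a[k], qtab$gene_b[k])
    l2 <- lookup(qtab$species_y[k], qtab$gene_c[k], qtab$gene_d[k])
    labs <- c(l1, l2)
    known <- labs[!is.na(labs)]
    if (length(known) == 2L && xor(known[1L] == "WGD", known[2L] == "WGD")) {
      cat_out[k] <- NA_character_       # conflicting annotation
      flag[k] <- TRUE
    } else if (any(known == "WGD")) {
      cat_out[k] <- "single_duplication_wgd"
    } else {
      cat_out[k] <- "single_duplication_other"
    }
  }
  qtab$category <- cat_out
  qtab$category_flagged <- flag
  qtab
}

#' Subsample quartets for downstream summaries
#'
#' Large families can contain many more quartets than the categorical
#' summaries need; this caps the table at `max_n` rows by a seeded uniform
#' subsample (families at or under the cap pass through unchanged).
#'
#' @param qtab Quartet table.
#' @param max_n Maximum number of quartets to keep (default 200).
#' @param seed Optional seed for the subsample.
#' @return A quartet table with at most `max_n` rows.
#' @export
sample_quartets <- function(qtab, max_n = 200L, seed = NULL) {
  if (nrow(qtab) <= max_n) return(qtab)
  keep <- with_local_seed(seed, sort(sample.int(nrow(qtab), max_n)))
  qtab[keep, , drop = FALSE]
}

#' Read a WGD annotation table
#'
#' TSV with columns species, gene_a, gene_b, label (header optional).
#'
#' @param path Path to the TSV file.
#' @return Data frame with those four character columns.
#' @export
read_wgd_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 4L)
    rf_stop("refates_format_error", "WGD table %s needs four columns", path)
  tab <- tab[, 1:4]
  if (tolower(trimws(tab[1L, 1L])) %in% c("species", "species_id"))
    tab <- tab[-1L, , drop = FALSE]
  names(tab) <- c("species", "gene_a", "gene_b", "label")
  tab
}

#' Asymmetry summary per quartet category
#'
#' Among quartets with significant fate similarity (`|Z_F| >` threshold),
#' the fraction that also shows significant asymmetry (`|Z_A| >` threshold),
#' with the standard error of the proportion `sqrt(p (1 - p) / n)`.
#'
#' @param qtab Quartet table with a `category` column (see
#'   [categorize_quartets()]).
#' @param z_threshold Significance threshold (default 1.96).
#' @return Data frame with one row per category: `category`, `n_significant`
#'   (denominator), `n_asymmetric`, `fraction`, `se`.  Categories with no
#'   significant quartet report `NA` fraction.
#' @export
asymmetry_summary <- function(qtab, z_threshold = 1.96) {
  qtab <- qtab[!is.na(qtab$category), , drop = FALSE]
  cats <- sort(unique(qtab$category))
  rows <- lapply(cats, function(cc) {
    sub <- qtab[qtab$category == cc & !is.na(qtab$Z_F) &
                  abs(qtab$Z_F) > z_threshold, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L)
      return(data.frame(category = cc, n_significant = 0L, n_asymmetric = 0L,
                        fraction = NA_real_, se = NA_real_))
    k <- sum(!is.na(sub$Z_A) & abs(sub$Z_A) > z_threshold)
    p <- k / n
    data.frame(category = cc, n_significant = n, n_asymmetric = k,
               fraction = p, se = sqrt(p * (1 - p) / n))
  })
  do.call(rbind, rows)
}

LOC_COMPARTMENTS <- c("Mito", "Chlo", "Secr", "Cyto")

#' Read a subcellular localization prediction table
#'
#' TSV with columns gene_id, compartment, reliability_class (header
#' optional).  Compartments follow the TargetP vocabulary: `Mito`
#' (mitochondrion), `Chlo` (chloroplast), `Secr` (secretory pathway) and
#' `Cyto` (cytoplasm / other; `Other` is accepted as a synonym).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene_id`, `compartment`,
#'   `reliability_class` (integer 1-5).
#' @export
read_localization_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 3L)
    rf_stop("refates_format_error",
            "localization table %s needs three columns", path)
  tab <- tab[, 1:3]
  if (tolower(trimws(tab[1L, 1L])) %in% c("gene", "gene_id", "geneid"))
    tab <- tab[-1L, , drop = FALSE]
  comp <- trimws(tab[[2L]])
  comp[tolower(comp) == "other"] <- "Cyto"
  comp <- LOC_COMPARTMENTS[match(tolower(comp), tolower(LOC_COMPARTMENTS))]
  if (anyNA(comp))
    rf_stop("refates_format_error",
            "unknown compartment in %s (expected %s)", path,
            paste(LOC_COMPARTMENTS, collapse = "/"))
  rc <- suppressWarnings(as.integer(tab[[3L]]))
  if (anyNA(rc) || any(rc < 1L) || any(rc > 5L))
    rf_stop("refates_format_error",
            "reliability class in %s must be an integer 1-5", path)
  data.frame(gene_id = trimws(tab[[1L]]), compartment = comp,
             reliability_class = rc, stringsAsFactors = FALSE)
}

# Configuration of four compartments (a, b, c, d) under a fate pairing.
# pairing "R" matches a~c, b~d; "S" matches a~d, b~c.
classify_localization <- function(la, lb, lc, ld, pairing) {
  pa <- if (pairing == "R") lc else ld     # partner of a
  pb <- if (pairing == "R") ld else lc
  xa <- if (pairing == "R") ld else lc     # crossed partner of a
  xb <- if (pairing == "R") lc else ld
  all4 <- c(la, lb, lc, ld)
  if (length(unique(all4)) == 1L) return("uniform")
  if (la == pa && lb == pb && la != lb) return("consistent")
  if (la == xa && lb == xb && la != lb) return("inconsistent")
  tt <- table(all4)
  if (length(tt) == 2L && min(tt) == 1L) return("single_distinct")
  "other"
}

#' Subcellular localization configuration of quartets
#'
#' For each quartet with a resolved pairing and a reliable localization
#' prediction for all four genes (reliability class strictly below
#' `max_rc`), labels the configuration: `uniform` (all four compartments
#' equal), `consistent` (compartments follow the fate pairing and differ
#' between fates — recurrent relocalization), `inconsistent` (compartments
#' follow the crossed pairing), `single_distinct` (exactly one gene deviates
#' from the other three) or `other`.
#'
#' @param qtab Quartet table.
#' @param loc Localization table from [read_localization_table()].
#' @param max_rc Reliability filter: all four genes need
#'   `reliability_class < max_rc` (default 3).
#' @return `qtab` with added columns `loc_config` (the label, or `NA` when
#'   the quartet is excluded) and `loc_excluded` (reason: `""`, `"tie"`,
#'   `"missing"`, `"unreliable"`).
#' @export
localization_configuration <- function(qtab, loc, max_rc = 3L) {
  comp <- stats::setNames(loc$compartment, loc$gene_id)
  rc <- stats::setNames(loc$reliability_class, loc$gene_id)
  config <- rep(NA_character_, nrow(qtab))
  reason <- character(nrow(qtab))
  for (k in seq_len(nrow(qtab))) {
    p <- qtab$pairing[k]
    if (is.na(p) || p == "tie") { reason[k] <- "tie"; next }
    g <- c(qtab$gene_a[k], qtab$gene_b[k], qtab$gene_c[k], qtab$gene_d[k])
    if (!all(g %in% names(comp))) { reason[k] <- "missing"; next }
    if (any(rc[g] >= max_rc)) { reason[k] <- "unreliable"; next }
    config[k] <- classify_localization(comp[g[1L]], comp[g[2L]],
                                       comp[g[3L]], comp[g[4L]], p)
  }
  qtab$loc_config <- config
  qtab$loc_excluded <- reason
  qtab
}

#' Localization configuration summary per quartet category
#'
#' Restricted to quartets with significant fate similarity, reports per
#' category the fraction of consistent and inconsistent configurations with
#' standard errors of the proportions.
#'
#' @param qtab Quartet table with `category` and `loc_config` columns.
#' @param z_threshold Significance threshold on `|Z_F|`.
#' @return Data frame: `category`, `n`, per-configuration counts and the
#'   `consistent`/`inconsistent` fractions with standard errors.
#' @export
localization_summary <- function(qtab, z_threshold = 1.96) {
  sub <- qtab[!is.na(qtab$category) & !is.na(qtab$loc_config) &
                !is.na(qtab$Z_F) & abs(qtab$Z_F) > z_threshold, , drop = FALSE]
  cats <- sort(unique(sub$category))
  labels <- c("consistent", "inconsistent", "uniform", "single_distinct", "other")
  rows <- lapply(cats, function(cc) {
    s <- sub[sub$category == cc, , drop = FALSE]
    n <- nrow(s)
    counts <- vapply(labels, function(lb) sum(s$loc_config == lb), integer(1L))
    pc <- counts[["consistent"]] / n
    pi_ <- counts[["inconsistent"]] / n
    out <- data.frame(category = cc, n = n, t(counts),
                      frac_consistent = pc,
                      se_consistent = sqrt(pc * (1 - pc) / n),
                      frac_inconsistent = pi_,
                      se_inconsistent = sqrt(pi_ * (1 - pi_) / n))
    out
  })
  do.call(rbind, rows)
}

PATTERN_CLASSES <- c("symmetric_support", "asym_support_side1",
                     "asym_support_side2", "symmetric_contradict",
                     "asym_contradict_side1", "asym_contradict_side2")
PATTERN_COLORS <- stats::setNames(
  c("yellow", "red", "pink", "blue", "cyan", "green"), PATTERN_CLASSES)

# Classify columns of one quartet relative to the fate-consistent
# orientation (vectorized over columns).  r1/r2 are the residues of the
# focal pair (fate side 1 and 2), s1/s2 those of the partner pair.  Gaps
# count as a 21st state so that shared absence (e.g. a target-peptide block
# present in only one fate) is itself a recurrent pattern; NA (ambiguous
# residue) makes a column unusable for that quartet.
classify_column_pattern <- function(r1, r2, s1, s2) {
  out <- rep("uninformative", length(r1))
  out[r1 == s1 & r2 == s2 & r1 != r2] <- "symmetric_support"
  out[r1 == s1 & r2 != s2 & r2 != r1 & s2 != r1] <- "asym_support_side1"
  out[r2 == s2 & r1 != s1 & r1 != r2 & s1 != r2] <- "asym_support_side2"
  out[r1 == s2 & r2 == s1 & r1 != r2] <- "symmetric_contradict"
  out[r1 == s2 & r2 != s1 & r2 != r1 & s1 != r1] <- "asym_contradict_side1"
  out[r2 == s1 & r1 != s2 & r1 != r2 & s2 != r2] <- "asym_contradict_side2"
  out[is.na(r1) | is.na(r2) | is.na(s1) | is.na(s2)] <- NA_character_
  out
}

#' Map the recurrent signal onto alignment columns
#'
#' For every paralog pair whose genes fall into the two prevailing fates,
#' each alignment column is classified over all quartets joining the pair to
#' pairs from *other* duplication blocks, relative to the fate-consistent
#' orientation: full two-sided matches support the fates symmetrically,
#' one-sided matches support one fate side, crossed matches contradict the
#' fate prediction.  Columns where support outweighs contradiction get warm
#' colors (yellow / red / pink for symmetric / side-1 / side-2 support),
#' columns where contradiction prevails get cold colors (blue / cyan /
#' green).  Gaps are treated as a 21st residue state, so shared
#' presence/absence blocks (target peptides, indels) register as recurrent
#' patterns.
#'
#' @param aln The (untrimmed) [family_alignment()].
#' @param pairs Paralog pairs.
#' @param dups Duplication clustering.
#' @param fates Robust fate set; its first prevailing fate id (sorted) is
#'   side 1.
#' @param prevailing Character vector of the two fate ids to orient by.
#' @return Data frame of class `column_annotation`: `species_id`, `column`
#'   (1-based), `class`, `color`, `n_support`, `n_contradict`.
#' @export
color_positions <- function(aln, pairs, dups, fates,
                            prevailing = NULL) {
  fate_of <- fates$fate_of
  if (is.null(prevailing)) {
    if (length(fates$clusters) < 2L)
      rf_stop("refates_degenerate_error",
              "need two fates to orient column patterns")
    prevailing <- sort(names(fates$clusters))[1:2]
  }
  prevailing <- sort(prevailing)
  coded <- encode_alignment(aln)           # gap stays a distinct state
  L <- ncol(coded)
  # orient each pair: side1 = gene in prevailing[1], side2 in prevailing[2]
  oriented <- lapply(seq_len(nrow(pairs)), function(i) {
    fa <- fate_of[pairs$gene_a[i]]; fb <- fate_of[pairs$gene_b[i]]
    if (is.na(fa) || is.na(fb)) return(NULL)
    if (fa == prevailing[1L] && fb == prevailing[2L])
      list(sp = pairs$species_id[i], g1 = pairs$gene_a[i], g2 = pairs$gene_b[i])
    else if (fb == prevailing[1L] && fa == prevailing[2L])
      list(sp = pairs$species_id[i], g1 = pairs$gene_b[i], g2 = pairs$gene_a[i])
    else NULL
  })
  oriented <- Filter(Negate(is.null), oriented)
  if (!length(oriented))
    rf_stop("refates_degenerate_error",
            "no paralog pair is split across the prevailing fates")
  block_of <- dups$membership
  out <- list()
  for (p in oriented) {
    partners <- Filter(function(q) block_of[q$sp] != block_of[p$sp], oriented)
    tally <- matrix(0L, length(PATTERN_CLASSES), L,
                    dimnames = list(PATTERN_CLASSES, NULL))
    for (q in partners) {
      cl <- classify_column_pattern(coded[p$g1, ], coded[p$g2, ],
                                    coded[q$g1, ], coded[q$g2, ])
      hit <- !is.na(cl) & cl != "uninformative"
      if (any(hit))
        tally[cbind(match(cl[hit], PATTERN_CLASSES), which(hit))] <-
          tally[cbind(match(cl[hit], PATTERN_CLASSES), which(hit))] + 1L
    }
    sup <- colSums(tally[1:3, , drop = FALSE])
    con <- colSums(tally[4:6, , drop = FALSE])
    cls <- rep("uninformative", L)
    for (col in seq_len(L)) {
      if (sup[col] > con[col]) {
        side <- tally[1:3, col]
        cls[col] <- PATTERN_CLASSES[1:3][which.max(side)]
      } else if (con[col] > sup[col]) {
        side <- tally[4:6, col]
        cls[col] <- PATTERN_CLASSES[4:6][which.max(side)]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      species_id = p$sp, column = seq_len(L), class = cls,
      color = ifelse(cls == "uninformative", "none", PATTERN_COLORS[cls]),
      n_support = as.integer(sup), n_contradict = as.integer(con),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("column_annotation", class(res))
  res
}

#' Recurrence logo: per-column class frequencies
#'
#' Aggregates the column annotations of all paralog pairs into the relative
#' frequency of each pattern class per column (the uninformative mass is
#' excluded, so columns sum to at most 1).
#'
#' @param annotations A [color_positions()] result.
#' @return Matrix of class `recurrence_logo` (6 pattern classes x columns).
#' @export
build_logo <- function(annotations) {
  stopifnot(inherits(annotations, "column_annotation"))
  n_pairs <- length(unique(annotations$species_id))
  L <- max(annotations$column)
  logo <- matrix(0, length(PATTERN_CLASSES), L,
                 dimnames = list(PATTERN_CLASSES, seq_len(L)))
  informative <- annotations$class != "uninformative"
  tab <- table(factor(annotations$class[informative],
                      levels = PATTERN_CLASSES),
               factor(annotations$column[informative], levels = seq_len(L)))
  logo[] <- as.numeric(tab) / n_pairs
  class(logo) <- c("recurrence_logo", class(logo))
  logo
}

#' Columns carrying a family-wide recurrent signal
#'
#' Summarizes a [color_positions()] annotation at the family level: a column
#' is called recurrent (warm) when its aggregate support frequency over
#' paralog pairs exceeds the contradiction frequency and reaches
#' `min_frequency` (a majority of pairs by default).  Per-pair warm calls at
#' a single column are noisy under neutral divergence; requiring a majority
#' of pairs suppresses that noise while retaining columns that drive the
#' fate signal across duplications.
#'
#' @param annotations A [color_positions()] result.
#' @param min_frequency Minimum fraction of pairs supporting (default 0.5).
#' @return Integer vector of 1-based column indices.
#' @export
recurrent_columns <- function(annotations, min_frequency = 0.5) {
  logo <- build_logo(annotations)
  warm <- colSums(logo[1:3, , drop = FALSE])
  cold <- colSums(logo[4:6, , drop = FALSE])
  which(warm > cold & warm >= min_frequency)
}

#' Plot a recurrence logo
#'
#' Stacked per-column barplot of the pattern-class frequencies, warm classes
#' up, cold classes down.
#'
#' @param logo A [build_logo()] matrix.
#' @param file Optional path; when given, a PDF device is opened.
#' @return `NULL`, invisibly.
#' @export
plot_logo <- function(logo, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 10, height = 3.5)
    on.exit(grDevices::dev.off())
  }
  warm <- logo[1:3, , drop = FALSE]
  cold <- logo[4:6, , drop = FALSE]
  L <- ncol(logo)
  ymax <- max(colSums(warm), 0.05)
  ymin <- max(colSums(cold), 0.05)
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(-ymin, ymax),
                 xlab = "alignment column", ylab = "pattern frequency",
                 main = "recurrent pattern logo")
  graphics::abline(h = 0, col = "grey40")
  for (col in seq_len(L)) {
    y0 <- 0
    for (i in 1:3) {
      h <- warm[i, col]
      if (h > 0) {
        graphics::rect(col - 0.45, y0, col + 0.45, y0 + h,
                       col = PATTERN_COLORS[i], border = NA)
        y0 <- y0 + h
      }
    }
    y0 <- 0
    for (i in 4:6) {
      h <- cold[i - 3, col]
      if (h > 0) {
        graphics::rect(col - 0.45, y0 - h, col + 0.45, y0,
                       col = PATTERN_COLORS[i], border = NA)
        y0 <- y0 - h
      }
    }
  }
  invisible(NULL)
}
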