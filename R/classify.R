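# DNA damage clustering and classification.
#
# Lesions are grouped into damage sites by a left-to-right sweep per chromatin
# segment (a new site opens when the next lesion lies more than dsb_window_bp
# beyond the current site's rightmost lesion). Within a site, a double-strand
# break (DSB) is a pairing of strand breaks on opposite strands within
# dsb_window_bp, assigned greedily by nearest pair with a leftmost-first
# tie-break so that each break is consumed by at most one DSB. Classes are
# hierarchical and mutually exclusive (DSB++ > DSB+ > DSB > SSB):
#   SSB    site carrying strand break(s) on one strand only;
#   DSB    site with exactly one break pairing and no companion lesion;
#   DSB+   a DSB accompanied by at least one additional lesion (break or base
#          lesion) within dsb_window_bp of the paired breaks;
#   DSB++  at least two DSBs within dsbpp_segment_bp of chromatin; proximity
#          is chained transitively on pair midpoints, merging sites if needed.
# Sites carrying only base lesions are never scored (tracked separately as
# diagnostics). Each DSB-bearing site is also typed by damage source:
# direct, indirect, hybrid (paired breaks of differing source) or mixed
# (paired breaks of one source with a companion lesion of the other).

#' Classifier configuration
#'
#' @param dsb_window_bp opposite-strand pairing window and companion-lesion
#'   window (bp), default 10.
#' @param dsbpp_segment_bp chromatin segment length within which two or more
#'   DSBs merge into a DSB++ (bp), default 100; must be >= `dsb_window_bp`.
#' @param dsbpp_tiling merge DSBs by proximity chaining on pair midpoints
#'   (`"sliding"`, default) or within fixed genome tiles of
#'   `dsbpp_segment_bp` (`"fixed"`).
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(dsb_window_bp = 10, dsbpp_segment_bp = 100,
                              dsbpp_tiling = c("sliding", "fixed")) {
  if (!is_count(dsb_window_bp) || dsb_window_bp <= 0)
    stop_invalid("dsb_window_bp must be a positive integer")
  if (!is_count(dsbpp_segment_bp) || dsbpp_segment_bp < dsb_window_bp)
    stop_invalid("dsbpp_segment_bp must be an integer >= dsb_window_bp")
  structure(list(dsb_window_bp = as.integer(dsb_window_bp),
                 dsbpp_segment_bp = as.integer(dsbpp_segment_bp),
                 dsbpp_tiling = match.arg(dsbpp_tiling)),
            class = "classifier_config")
}

as_lesion_frame <- function(x) {
  if (inherits(x, "lesion_set")) x$lesions
  else if (is.data.frame(x)) x
  else stop_invalid("expected a lesion_set or a lesion data.frame")
}

#' Cluster lesions into damage sites
#'
#' Single left-to-right sweep per segment: consecutive lesions separated by at
#' most `dsb_window_bp` belong to the same site. Lesions never co-cluster
#' across segment boundaries.
#'
#' @param x a `lesion_set` or lesion data.frame (columns segment_id, pos_bp,
#'   strand, kind, source).
#' @param config a [classifier_config()].
#' @return the lesion data.frame, sorted by (segment_id, pos_bp), with a
#'   `site_id` column (consecutive integers) and a `lesion_id` column keyed to
#'   the input row order.
#' @export
cluster_lesions <- function(x, config = classifier_config()) {
  l <- as_lesion_frame(x)
  stopifnot(inherits(config, "classifier_config"))
  if (nrow(l) == 0L) {
    l$site_id <- integer(0); l$lesion_id <- integer(0)
    return(l)
  }
  l$lesion_id <- seq_len(nrow(l))
  ord <- order(l$segment_id, l$pos_bp)
  l <- l[ord, , drop = FALSE]
  gap_new <- c(TRUE, diff(l$segment_id) != 0L | diff(l$pos_bp) > config$dsb_window_bp)
  l$site_id <- cumsum(gap_new)
  rownames(l) <- NULL
  l
}

# Greedy nearest-pair matching of opposite-strand break positions within one
# site. Ties on distance are broken leftmost-first (smallest left endpoint,
# then smallest strand-1 position, then smallest strand-2 position, then
# source labels) -- a total order on the lesion attributes, so the pairing is
# invariant to the input row order. Returns a 2-column matrix of indices into
# (pos1, pos2).
greedy_pair_breaks <- function(pos1, pos2, window, src1 = NULL, src2 = NULL) {
  n1 <- length(pos1); n2 <- length(pos2)
  if (n1 == 0L || n2 == 0L) return(matrix(integer(0), ncol = 2))
  if (is.null(src1)) src1 <- rep("", n1)
  if (is.null(src2)) src2 <- rep("", n2)
  avail1 <- rep(TRUE, n1); avail2 <- rep(TRUE, n2)
  pairs <- matrix(integer(0), ncol = 2)
  d <- abs(outer(pos1, pos2, "-"))
  repeat {
    dd <- d
    dd[!avail1, ] <- Inf
    dd[, !avail2] <- Inf
    m <- min(dd)
    if (!is.finite(m) || m > window) break
    hits <- which(dd == m, arr.ind = TRUE)
    left <- pmin(pos1[hits[, 1]], pos2[hits[, 2]])
    sel <- order(left, pos1[hits[, 1]], pos2[hits[, 2]],
                 src1[hits[, 1]], src2[hits[, 2]])[1]
    i <- hits[sel, 1]; j <- hits[sel, 2]
    pairs <- rbind(pairs, c(i, j))
    avail1[i] <- FALSE; avail2[j] <- FALSE
  }
  pairs
}

#' Classify damage sites
#'
#' Runs the full classification: sweep clustering ([cluster_lesions()]), greedy
#' DSB pairing, hierarchical complexity labels (DSB++ > DSB+ > DSB > SSB) and
#' per-site source typing.
#'
#' @inheritParams cluster_lesions
#' @return an object of class `damage_sites`: list with
#'   \describe{
#'     \item{sites}{data.frame, one row per site: site_id, segment_id,
#'       start_bp, end_bp, n_lesions, n_breaks, n_pairs, class (one of
#'       `"SSB"`, `"DSB"`, `"DSB_plus"`, `"DSB_plusplus"`, `"base_only"`),
#'       source_type (`"direct"`, `"indirect"`, `"hybrid"`, `"mixed"`,
#'       `"none"`).}
#'     \item{pairs}{data.frame, one row per DSB pairing: site_id, segment_id,
#'       lesion ids and positions of the paired breaks, midpoint, and the
#'       DSB++ group id (`NA` when not merged).}
#'     \item{lesions}{the clustered lesion table.}
#'     \item{n_dsbpp_groups}{number of merged DSB++ entities.}
#'     \item{dose_Gy, genome}{carried through from the lesion set when
#'       available (else `NA`/`NULL`).}
#'   }
#' @export
classify_damage <- function(x, config = classifier_config()) {
  l <- cluster_lesions(x, config)
  w <- config$dsb_window_bp
  dose <- if (inherits(x, "lesion_set")) x$dose_Gy else NA_real_
  genome <- if (inherits(x, "lesion_set")) x$genome else NULL

  n_sites <- if (nrow(l)) max(l$site_id) else 0L
  empty_sites <- data.frame(site_id = integer(0), segment_id = integer(0),
                            start_bp = integer(0), end_bp = integer(0),
                            n_lesions = integer(0), n_breaks = integer(0),
                            n_pairs = integer(0), class = character(0),
                            source_type = character(0), stringsAsFactors = FALSE)
  empty_pairs <- data.frame(site_id = integer(0), segment_id = integer(0),
                            lesion_a = integer(0), lesion_b = integer(0),
                            pos_a = integer(0), pos_b = integer(0),
                            center_bp = numeric(0), group_id = integer(0),
                            stringsAsFactors = FALSE)
  if (n_sites == 0L) {
    return(structure(list(sites = empty_sites, pairs = empty_pairs, lesions = l,
                          n_dsbpp_groups = 0L, dose_Gy = dose, genome = genome),
                     class = "damage_sites"))
  }

  is_break <- l$kind == "strand_break"
  agg <- rowsum(cbind(one = rep(1L, nrow(l)),
                      brk = as.integer(is_break),
                      b1 = as.integer(is_break & l$strand == 1L),
                      b2 = as.integer(is_break & l$strand == 2L)),
                l$site_id)
  site_id <- as.integer(rownames(agg))
  seg_of_site <- l$segment_id[!duplicated(l$site_id)]
  start_bp <- tapply(l$pos_bp, l$site_id, min)
  end_bp <- tapply(l$pos_bp, l$site_id, max)

  sites <- data.frame(site_id = site_id, segment_id = seg_of_site,
                      start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
                      n_lesions = as.integer(agg[, "one"]),
                      n_breaks = as.integer(agg[, "brk"]),
                      n_pairs = 0L, class = "base_only", source_type = "none",
                      stringsAsFactors = FALSE)
  sites$class[sites$n_breaks > 0L] <- "SSB"

  candidates <- site_id[agg[, "b1"] > 0L & agg[, "b2"] > 0L]
  pair_rows <- list()
  plus_flag <- logical(n_sites)
  src_of_site <- rep("none", n_sites)

  if (length(candidates)) {
    idx_by_site <- split(seq_len(nrow(l)), l$site_id)
    for (s in candidates) {
      rows <- idx_by_site[[as.character(s)]]
      pos <- l$pos_bp[rows]
      brk <- l$kind[rows] == "strand_break"
      i1 <- rows[brk & l$strand[rows] == 1L]
      i2 <- rows[brk & l$strand[rows] == 2L]
      pm <- greedy_pair_breaks(l$pos_bp[i1], l$pos_bp[i2], w,
                               l$source[i1], l$source[i2])
      if (nrow(pm) == 0L) next
      a <- i1[pm[, 1]]; b <- i2[pm[, 2]]
      lo <- pmin(l$pos_bp[a], l$pos_bp[b])
      hi <- pmax(l$pos_bp[a], l$pos_bp[b])
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        site_id = s, segment_id = l$segment_id[rows[1]],
        lesion_a = l$lesion_id[a], lesion_b = l$lesion_id[b],
        pos_a = l$pos_bp[a], pos_b = l$pos_bp[b],
        center_bp = (lo + hi) / 2, group_id = NA_integer_,
        stringsAsFactors = FALSE)
      sites$n_pairs[s] <- nrow(pm)  # site ids are consecutive 1..n_sites

      # companion lesion within the window of any pairing -> DSB+
      companion <- FALSE
      src <- "none"
      paired_src <- character(0)
      acc_src <- character(0)
      for (k in seq_len(nrow(pm))) {
        others <- setdiff(rows, c(a[k], b[k]))
        if (length(others)) {
          p <- l$pos_bp[others]
          dist <- pmax(0, pmax(lo[k] - p, p - hi[k]))
          if (any(dist <= w)) companion <- TRUE
        }
        paired_src <- c(paired_src, l$source[c(a[k], b[k])])
      }
      plus_flag[s] <- companion
      acc_rows <- setdiff(rows, c(a, b))
      acc_src <- l$source[acc_rows]
      if (length(unique(paired_src)) > 1L) {
        src <- "hybrid"
      } else if (length(acc_src) == 0L || all(acc_src == paired_src[1])) {
        src <- paired_src[1]
      } else {
        src <- "mixed"
      }
      src_of_site[s] <- src
    }
  }

  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else empty_pairs

  # DSB++ merging: chain pair midpoints within dsbpp_segment_bp per segment
  n_groups <- 0L
  dsbpp_sites <- integer(0)
  if (nrow(pairs)) {
    ordp <- order(pairs$segment_id, pairs$center_bp)
    pairs <- pairs[ordp, , drop = FALSE]
    if (config$dsbpp_tiling == "sliding") {
      chain_new <- c(TRUE, diff(pairs$segment_id) != 0L |
                       diff(pairs$center_bp) > config$dsbpp_segment_bp)
      grp <- cumsum(chain_new)
    } else {
      grp <- as.integer(factor(paste(pairs$segment_id,
                                     pairs$center_bp %/% config$dsbpp_segment_bp)))
    }
    sizes <- table(grp)
    big <- as.integer(names(sizes)[sizes >= 2L])
    pairs$group_id <- ifelse(grp %in% big, match(grp, big), NA_integer_)
    n_groups <- length(big)
    dsbpp_sites <- unique(pairs$site_id[!is.na(pairs$group_id)])
    rownames(pairs) <- NULL
  }

  has_pair <- sites$n_pairs > 0L
  sites$class[has_pair] <- "DSB"
  sites$class[has_pair & plus_flag[sites$site_id]] <- "DSB_plus"
  sites$class[sites$site_id %in% dsbpp_sites] <- "DSB_plusplus"
  sites$source_type <- src_of_site[sites$site_id]

  structure(list(sites = sites, pairs = pairs, lesions = l,
                 n_dsbpp_groups = n_groups, dose_Gy = dose, genome = genome),
            class = "damage_sites")
}

#' @export
print.damage_sites <- function(x, ...) {
  cat(sprintf("<damage_sites> %d lesions in %d sites: %s; %d DSB pairings, %d DSB++ groups\n",
              nrow(x$lesions), nrow(x$sites),
              paste(names(table(x$sites$class)), table(x$sites$class),
                    sep = "=", collapse = ", "),
              nrow(x$pairs), x$n_dsbpp_groups))
  invisible(x)
}

#' Source type of a single damage site
#'
#' Applies the source-typing rules to one site given its paired-break sources
#' and accompanying-lesion sources: all direct -> `"direct"`, all indirect ->
#' `"indirect"`, paired breaks of differing source -> `"hybrid"`, paired
#' breaks of one source with an accompanying lesion of the other ->
#' `"mixed"`. A site without a DSB pairing has source type `"none"`.
#'
#' @param paired_sources character vector of sources (`"direct"`/`"indirect"`)
#'   of the paired break lesions (length 2 per DSB pairing).
#' @param accompanying_sources sources of the site's remaining lesions.
#' @return one of `"direct"`, `"indirect"`, `"hybrid"`, `"mixed"`, `"none"`.
#' @export
classify_source <- function(paired_sources, accompanying_sources = character(0)) {
  if (length(paired_sources) == 0L) return("none")
  if (length(unique(paired_sources)) > 1L) return("hybrid")
  if (length(accompanying_sources) == 0L ||
      all(accompanying_sources == paired_sources[1])) return(paired_sources[1])
  "mixed"
}

#' Tally damage counts, yields and ratios
#'
#' Aggregates classified sites into the standard damage summary. Conventions:
#' a DSB++ entity contributes its constituent pairings to the DSB total and
#' once to the complex count (switch with `dsbpp_counts`); the strand-break
#' denominator "SB" for fraction columns is SSB sites + total DSBs.
#'
#' @param sites a `damage_sites` object from [classify_damage()].
#' @param dose_Gy absorbed dose (Gy), > 0 for yield normalization; defaults to
#'   the dose recorded in `sites`.
#' @param genome a [genome_model()]; defaults to the genome recorded in
#'   `sites`.
#' @param dsbpp_counts `"constituents"` (default): each pairing inside a DSB++
#'   counts toward the DSB total; `"once"`: a DSB++ entity counts as a single
#'   DSB.
#' @return an object of class `damage_tally`: list with `counts` (SSB, DSB,
#'   DSB_plus, DSB_plusplus, DSB_D, DSB_I, DSB_HYB, DSB_MIX, base_only_sites,
#'   n_lesions), `yields` (SSB_per_Gy_Gbps, DSB_per_Gy_Gbps) and `ratios`
#'   (SSB_over_DSB, DSB_fraction_of_SB, complex_DSB_fraction_of_SB,
#'   complex_DSB_fraction_of_DSB); ratios are `NA` when their denominator is
#'   zero.
#' @export
tally_damage <- function(sites, dose_Gy = NULL, genome = NULL,
                         dsbpp_counts = c("constituents", "once")) {
  stopifnot(inherits(sites, "damage_sites"))
  dsbpp_counts <- match.arg(dsbpp_counts)
  if (is.null(dose_Gy)) dose_Gy <- sites$dose_Gy
  if (is.null(genome)) genome <- sites$genome
  if (is.null(dose_Gy) || is.na(dose_Gy) || dose_Gy <= 0)
    stop_invalid("dose_Gy must be > 0 to normalize yields")
  if (is.null(genome)) stop_invalid("a genome_model is required to normalize yields")

  cls <- sites$sites$class
  src <- sites$sites$source_type
  n_ssb <- sum(cls == "SSB")
  n_plus <- sum(cls == "DSB_plus")
  n_pp <- sites$n_dsbpp_groups
  n_plain <- sum(cls == "DSB")
  dsb_total <- if (dsbpp_counts == "constituents") nrow(sites$pairs)
               else n_plain + n_plus + n_pp
  bearing <- cls %in% c("DSB", "DSB_plus", "DSB_plusplus")
  counts <- c(SSB = n_ssb, DSB = n_plain, DSB_plus = n_plus, DSB_plusplus = n_pp,
              DSB_total = dsb_total,
              DSB_D = sum(src == "direct" & bearing),
              DSB_I = sum(src == "indirect" & bearing),
              DSB_HYB = sum(src == "hybrid" & bearing),
              DSB_MIX = sum(src == "mixed" & bearing),
              base_only_sites = sum(cls == "base_only"),
              n_lesions = nrow(sites$lesions))
  norm <- dose_Gy * genome$genome_size_Gbps
  yields <- c(SSB_per_Gy_Gbps = n_ssb / norm, DSB_per_Gy_Gbps = dsb_total / norm)
  sb <- n_ssb + dsb_total
  complex <- n_plus + n_pp
  ratios <- c(SSB_over_DSB = if (dsb_total > 0) n_ssb / dsb_total else NA_real_,
              DSB_fraction_of_SB = if (sb > 0) dsb_total / sb else NA_real_,
              complex_DSB_fraction_of_SB = if (sb > 0) complex / sb else NA_real_,
              complex_DSB_fraction_of_DSB = if (dsb_total > 0) complex / dsb_total else NA_real_)
  structure(list(counts = counts, yields = yields, ratios = ratios,
                 dose_Gy = dose_Gy, genome_size_Gbps = genome$genome_size_Gbps,
                 dsbpp_counts = dsbpp_counts),
            class = "damage_tally")
}

#' @export
print.damage_tally <- function(x, ...) {
  cat(sprintf("<damage_tally> dose %.3g Gy, genome %.2f Gbps\n", x$dose_Gy, x$genome_size_Gbps))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  cat(sprintf("  yields: SSB %.3f /Gy/Gbps, DSB %.3f /Gy/Gbps\n",
              x$yields["SSB_per_Gy_Gbps"], x$yields["DSB_per_Gy_Gbps"]))
  cat(sprintf("  SSB/DSB %.2f, DSB/SB %.3f, complex/SB %.4f, complex/DSB %.3f\n",
              x$ratios["SSB_over_DSB"], x$ratios["DSB_fraction_of_SB"],
              x$ratios["complex_DSB_fraction_of_SB"], x$ratios["complex_DSB_fraction_of_DSB"]))
  invisible(x)
}

#' Combine tallies from repeated exposures
#'
#' Sums counts across independent exposures (e.g. one per simulated nucleus)
#' and renormalizes yields by the summed dose, so the result is the tally of
#' the pooled experiment.
#'
#' @param tallies list of `damage_tally` objects sharing a genome size and
#'   DSB++ counting convention.
#' @return a `damage_tally`.
#' @export
combine_tallies <- function(tallies) {
  stopifnot(length(tallies) > 0L, all(vapply(tallies, inherits, TRUE, "damage_tally")))
  counts <- Reduce(`+`, lapply(tallies, `[[`, "counts"))
  dose_total <- sum(vapply(tallies, `[[`, 0, "dose_Gy"))
  gbps <- tallies[[1]]$genome_size_Gbps
  norm <- dose_total * gbps
  dsb_total <- counts[["DSB_total"]]
  n_ssb <- counts[["SSB"]]
  sb <- n_ssb + dsb_total
  complex <- counts[["DSB_plus"]] + counts[["DSB_plusplus"]]
  structure(list(counts = counts,
                 yields = c(SSB_per_Gy_Gbps = n_ssb / norm,
                            DSB_per_Gy_Gbps = dsb_total / norm),
                 ratios = c(SSB_over_DSB = if (dsb_total > 0) n_ssb / dsb_total else NA_real_,
                            DSB_fraction_of_SB = if (sb > 0) dsb_total / sb else NA_real_,
                            complex_DSB_fraction_of_SB = if (sb > 0) complex / sb else NA_real_,
                            complex_DSB_fraction_of_DSB = if (dsb_total > 0) complex / dsb_total else NA_real_),
                 dose_Gy = dose_total, genome_size_Gbps = gbps,
                 dsbpp_counts = tallies[[1]]$dsbpp_counts),
            class = "damage_tally")
}

#' Write a damage tally as a one-row CSV
#'
#' @param tally a `damage_tally`.
#' @param path output file; append with `append = TRUE`.
#' @param label optional exposure label written in the first column.
#' @param append append to an existing file without rewriting the header.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tally, path, label = NA_character_, append = FALSE) {
  stopifnot(inherits(tally, "damage_tally"))
  row <- data.frame(label = label, dose_Gy = tally$dose_Gy,
                    t(tally$counts), t(tally$yields), t(tally$ratios),
                    check.names = TRUE)
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, qmethod = "double")
  invisible(path)
}
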