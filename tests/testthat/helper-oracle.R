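# Exhaustive brute-force evaluator of the damage-classification rules,
# implemented independently of the package's sweep algorithm: site partition
# by union-find over all lesion pairs, DSB pairing by repeatedly rescanning
# the full candidate-pair list, DSB++ merging by union-find over pair
# midpoints. O(n^2) or worse throughout -- usable only on small lesion sets,
# which is the point.

oracle_classify <- function(les, dsb_window = 10L, dsbpp_segment = 100L) {
  n <- nrow(les)
  les$lesion_id <- seq_len(n)
  if (n == 0L) {
    return(list(partition = list(), classes = character(0),
                sources = character(0), pairs = matrix(integer(0), ncol = 2),
                n_pairs = 0L, n_pp_groups = 0L,
                counts = c(SSB = 0L, DSB = 0L, DSB_plus = 0L, DSB_plusplus = 0L)))
  }

  # --- union-find site partition over all pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && les$segment_id[i] == les$segment_id[j] &&
        abs(les$pos_bp[i] - les$pos_bp[j]) <= dsb_window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), root)

  # --- greedy nearest-pair DSB matching, rescanning candidates every step
  all_pairs <- list()
  site_class <- character(length(groups))
  site_source <- character(length(groups))
  names(site_class) <- names(site_source) <- names(groups)
  site_pairs <- vector("list", length(groups))
  names(site_pairs) <- names(groups)

  for (g in names(groups)) {
    idx <- groups[[g]]
    brk <- idx[les$kind[idx] == "strand_break"]
    s1 <- brk[les$strand[brk] == 1L]
    s2 <- brk[les$strand[brk] == 2L]
    used <- integer(0)
    gp <- list()
    repeat {
      cand <- expand.grid(a = setdiff(s1, used), b = setdiff(s2, used))
      if (nrow(cand) == 0L) break
      cand$dist <- abs(les$pos_bp[cand$a] - les$pos_bp[cand$b])
      cand <- cand[cand$dist <= dsb_window, , drop = FALSE]
      if (nrow(cand) == 0L) break
      cand$left <- pmin(les$pos_bp[cand$a], les$pos_bp[cand$b])
      o <- order(cand$dist, cand$left, les$pos_bp[cand$a], les$pos_bp[cand$b],
                 les$source[cand$a], les$source[cand$b])
      pick <- cand[o[1], ]
      gp[[length(gp) + 1L]] <- c(pick$a, pick$b)
      used <- c(used, pick$a, pick$b)
    }
    site_pairs[[g]] <- gp
    all_pairs <- c(all_pairs, gp)

    # complexity (before DSB++ merging) and source
    if (length(gp) > 0L) {
      plus <- FALSE
      for (p in gp) {
        lo <- min(les$pos_bp[p]); hi <- max(les$pos_bp[p])
        others <- setdiff(idx, p)
        for (q in others) {
          pq <- les$pos_bp[q]
          dist <- if (pq < lo) lo - pq else if (pq > hi) pq - hi else 0
          if (dist <= dsb_window) { plus <- TRUE; break }
        }
        if (plus) break
      }
      site_class[g] <- if (plus) "DSB_plus" else "DSB"
      paired <- unlist(gp)
      ps <- les$source[paired]
      acc <- les$source[setdiff(idx, paired)]
      site_source[g] <- if (length(unique(ps)) > 1L) "hybrid"
        else if (length(acc) == 0L || all(acc == ps[1])) ps[1]
        else "mixed"
    } else if (length(brk) > 0L) {
      site_class[g] <- "SSB"; site_source[g] <- "none"
    } else {
      site_class[g] <- "base_only"; site_source[g] <- "none"
    }
  }

  # --- DSB++ merging: union-find over pair midpoints per segment
  np <- length(all_pairs)
  n_pp_groups <- 0L
  if (np > 0L) {
    mid <- vapply(all_pairs, function(p) mean(les$pos_bp[p]), 0)
    seg <- vapply(all_pairs, function(p) les$segment_id[p[1]], 0L)
    pp_parent <- seq_len(np)
    pfind <- function(i) { while (pp_parent[i] != i) i <- pp_parent[i]; i }
    for (i in seq_len(np)) for (j in seq_len(np)) {
      if (i < j && seg[i] == seg[j] && abs(mid[i] - mid[j]) <= dsbpp_segment) {
        ri <- pfind(i); rj <- pfind(j)
        if (ri != rj) pp_parent[ri] <- rj
      }
    }
    proot <- vapply(seq_len(np), pfind, 0L)
    tab <- table(proot)
    big <- names(tab)[tab >= 2L]
    n_pp_groups <- length(big)
    if (n_pp_groups > 0L) {
      pp_pairs <- which(as.character(proot) %in% big)
      # any site owning one of these pairs becomes DSB_plusplus
      for (g in names(groups)) {
        if (length(site_pairs[[g]]) == 0L) next
        owned <- vapply(site_pairs[[g]], function(p)
          any(vapply(pp_pairs, function(k) identical(sort(all_pairs[[k]]), sort(p)), TRUE)),
          TRUE)
        if (any(owned)) site_class[g] <- "DSB_plusplus"
      }
    }
  }

  pair_mat <- if (np > 0L)
    t(vapply(all_pairs, function(p) sort(les$lesion_id[p]), integer(2)))
  else matrix(integer(0), ncol = 2)

  list(partition = canonical_partition(lapply(groups, function(ix) les$lesion_id[ix])),
       classes = site_class[order(vapply(groups, min, 0L))],
       sources = site_source[order(vapply(groups, min, 0L))],
       pairs = pair_mat[order(pair_mat[, 1], pair_mat[, 2]), , drop = FALSE],
       n_pairs = np, n_pp_groups = n_pp_groups,
       counts = c(SSB = sum(site_class == "SSB"),
                  DSB = sum(site_class == "DSB"),
                  DSB_plus = sum(site_class == "DSB_plus"),
                  DSB_plusplus = n_pp_groups))
}

# package-result counterpart in the same canonical form
package_classify_canonical <- function(les, config = classifier_config()) {
  res <- classify_damage(les, config)
  ids_by_site <- split(res$lesions$lesion_id, res$lesions$site_id)
  part <- canonical_partition(ids_by_site)
  # order site rows by smallest member lesion id to align with the oracle
  first_id <- vapply(split(res$lesions$lesion_id, res$lesions$site_id), min, 0L)
  o <- order(first_id)
  pm <- cbind(pmin(res$pairs$lesion_a, res$pairs$lesion_b),
              pmax(res$pairs$lesion_a, res$pairs$lesion_b))
  list(partition = part,
       classes = res$sites$class[o],
       sources = res$sites$source_type[o],
       pairs = pm[order(pm[, 1], pm[, 2]), , drop = FALSE],
       n_pairs = nrow(res$pairs),
       n_pp_groups = res$n_dsbpp_groups,
       counts = c(SSB = sum(res$sites$class == "SSB"),
                  DSB = sum(res$sites$class == "DSB"),
                  DSB_plus = sum(res$sites$class == "DSB_plus"),
                  DSB_plusplus = res$n_dsbpp_groups))
}

expect_matches_oracle <- function(les, dsb_window = 10L, dsbpp_segment = 100L) {
  orc <- oracle_classify(les, dsb_window, dsbpp_segment)
  pkg <- package_classify_canonical(
    les, classifier_config(dsb_window, dsbpp_segment))
  expect_identical(pkg$partition, orc$partition)
  expect_identical(unname(pkg$classes), unname(orc$classes))
  expect_identical(unname(pkg$sources), unname(orc$sources))
  expect_identical(unname(pkg$pairs), unname(orc$pairs))
  expect_identical(pkg$n_pp_groups, orc$n_pp_groups)
  invisible(TRUE)
}
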