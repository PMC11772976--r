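# Small constructors shared across tests.

# one lesion row
L <- function(pos, strand, kind = "strand_break", source = "direct", segment = 1L) {
  data.frame(segment_id = as.integer(segment), pos_bp = as.integer(pos),
             strand = as.integer(strand), kind = kind, source = source,
             track_id = 1L, stringsAsFactors = FALSE)
}

lesions <- function(...) do.call(rbind, list(...))

# random lesion set on few segments, positions packed to force interactions
random_lesions <- function(n, max_pos = 250L, n_segments = 1L) {
  data.frame(segment_id = sample.int(n_segments, n, replace = TRUE),
             pos_bp = sample.int(max_pos + 1L, n, replace = TRUE) - 1L,
             strand = sample(1:2, n, replace = TRUE),
             kind = sample(c("strand_break", "base_lesion"), n, replace = TRUE),
             source = sample(c("direct", "indirect"), n, replace = TRUE),
             track_id = sample.int(5L, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small fast geometry for generator tests
small_nucleus <- function() nucleus_geometry(4, 3, 2)

# canonical representation of a site partition: list of sorted lesion-id
# vectors, sorted by first element
canonical_partition <- function(ids_by_site) {
  parts <- lapply(ids_by_site, function(v) sort(as.integer(v)))
  unname(parts[order(vapply(parts, `[`, 0L, 1L))])
}
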