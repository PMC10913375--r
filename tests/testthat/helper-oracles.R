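# Desk-scale fixtures and independent brute-force oracles used across tests.

toy_replicon <- function(length_bp = 10000, circular = TRUE,
                         ter_start = 4800, ter_end = 5199, dif_pos = 5000) {
  replicon_spec("toy", "TOY", length_bp, circular = circular,
                ter_start = ter_start, ter_end = ter_end, dif_pos = dif_pos,
                ori_pos = 1)
}

random_mappings <- function(replicon, n, read_len = 50, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(replicon$length_bp, n, replace = TRUE)
    read_mappings(tibble::tibble(start = start, end = start + read_len - 1,
                                 strand = sample(c("+", "-"), n, TRUE)),
                  replicon)
  })
}

# positions covered by one read, as explicit genome positions
read_positions <- function(start, end, L) {
  if (end >= start) start:end else c(start:L, 1:end)
}

# position-by-position depth oracle
oracle_coverage <- function(mappings) {
  rp <- replicon_of(mappings)
  depth <- integer(rp$length_bp)
  for (i in seq_len(nrow(mappings))) {
    p <- read_positions(mappings$start[i], mappings$end[i], rp$length_bp)
    depth[p] <- depth[p] + 1L
  }
  depth
}

# per-read membership-loop region count oracle (start-assignment rule)
oracle_count <- function(mappings, region) {
  rp <- replicon_of(mappings)
  n <- 0L
  for (s in mappings$start) {
    inside <- if (region$wraps) s >= region$start || s <= region$end
              else s >= region$start && s <= region$end
    if (inside) n <- n + 1L
  }
  n
}

# direct window-mean recomputation oracle
oracle_windows <- function(track, window_bp, step_bp) {
  rp <- track$replicon
  L <- length(track$depth)
  centers <- seq.int(1L, L, by = step_bp)
  vapply(centers, function(ctr) {
    lo <- ctr - (window_bp - 1L) %/% 2L
    hi <- lo + window_bp - 1L
    if (rp$circular) {
      idx <- ((lo:hi - 1L) %% L) + 1L
      mean(track$depth[idx])
    } else {
      mean(track$depth[max(lo, 1L):min(hi, L)])
    }
  }, numeric(1))
}

# rotate a mapping set and its replicon anchors by a constant offset
rotate_world <- function(mappings, offset) {
  rp <- replicon_of(mappings)
  L <- rp$length_bp
  rot <- function(p) if (is.null(p)) NULL else ((p - 1 + offset) %% L) + 1
  rp2 <- replicon_spec(rp$name, rp$accession, L, circular = rp$circular,
                       ter_start = rot(rp$ter_start), ter_end = rot(rp$ter_end),
                       dif_pos = rot(rp$dif_pos), ori_pos = rot(rp$ori_pos))
  read_mappings(tibble::tibble(start = rot(mappings$start),
                               end = rot(mappings$end),
                               strand = mappings$strand), rp2)
}
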