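# Shared builders for small, fast synthetic inputs.

# compact mixed scene; noise-free by default so recovery is exact
small_scene <- function(seed, noise_sd = 0, ...) {
  scene_spec(field_shape = c(320L, 320L),
             n_uninfected_sar11 = 8, n_infected_sar11 = 4, n_zombie = 3,
             n_other_bacteria = 5, n_free_phage = 6,
             dividing_fraction = 0.3, noise_sd = noise_sd, seed = seed,
             ...)
}

truth_counts <- function(truth) {
  c(sar11 = sum(truth$class %in% c("uninfected_sar11", "infected_sar11")),
    infected = sum(truth$class == "infected_sar11"),
    zombie = sum(truth$class == "zombie"),
    total = sum(truth$class != "free_phage"),
    free_phage = sum(truth$class == "free_phage"),
    dividing = sum(truth$dividing))
}

result_counts <- function(res) {
  c(sar11 = res$sar11_cells, infected = res$infected_cells,
    zombie = res$zombie_cells, total = res$total_cells,
    free_phage = res$free_phage_objects, dividing = res$dividing_cells)
}

# genome of alternating conserved / scrambled 156-bp blocks: exactly
# n_islands windows (length 156, step 156) match the reference at >= 90%
island_genome <- function(n_islands = 12, block = 156L, seed = 99) {
  set.seed(seed)
  base_p <- c(A = 0.335, C = 0.165, G = 0.165, T = 0.335)
  blocks_g <- character(2 * n_islands)
  blocks_r <- character(2 * n_islands)
  for (i in seq_len(n_islands)) {
    isl <- paste(sample(names(base_p), block, replace = TRUE,
                        prob = base_p), collapse = "")
    scr_g <- paste(sample(names(base_p), block, replace = TRUE,
                          prob = base_p), collapse = "")
    scr_r <- paste(sample(names(base_p), block, replace = TRUE,
                          prob = base_p), collapse = "")
    blocks_g[2 * i - 1] <- isl;   blocks_g[2 * i] <- scr_g
    blocks_r[2 * i - 1] <- isl;   blocks_r[2 * i] <- scr_r
  }
  list(genome = paste(blocks_g, collapse = ""),
       reference = paste(blocks_r, collapse = ""),
       island_starts0 = (seq_len(n_islands) - 1L) * 2L * block)
}

# exhaustive O(L * W) candidate scan: the independent enumeration oracle
exhaustive_enumerate <- function(genome, reference, cfg) {
  L <- nchar(genome)
  out <- data.frame(start = integer(0), length = integer(0))
  for (len in cfg$length_set) {
    if (len > L) next
    for (s0 in seq(0L, L - len, by = cfg$step)) {
      win <- substr(genome, s0 + 1, s0 + len)
      gc <- gc_fraction(win)
      if (gc < cfg$gc_band[1] || gc > cfg$gc_band[2]) next
      if (window_identity(win, reference) < cfg$identity_min) next
      out <- rbind(out, data.frame(start = s0, length = len))
    }
  }
  out
}

# independent stack-based flood fill, the segmentation oracle
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  offs <- if (connectivity == 8)
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    stack <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- cur
    while (nrow(stack)) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (j in seq_len(nrow(offs))) {
        rr <- p[1] + offs[j, 1]; cc <- p[2] + offs[j, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack <- rbind(stack, c(rr, cc))
        }
      }
    }
  }
  lab
}

# introduce exactly m mismatches into a sequence at given positions
mutate_at <- function(seq, positions) {
  for (p in positions)
    substr(seq, p, p) <- chartr("ACGT", "CGTA", substr(seq, p, p))
  seq
}
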