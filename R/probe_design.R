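#' GC fraction of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T); `N` bases are excluded from numerator and
#' denominator. Polynucleotide FISH probes are designed with a GC content
#' similar to their target phage genomes.
#'
#' @param seq a single nucleotide string over A/C/G/T/N (case-insensitive).
#' @return GC fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("empty sequence")
  s <- toupper(seq)
  counts <- table(strsplit(s, "")[[1]])
  bad <- setdiff(names(counts), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("invalid characters in sequence: ",
                        paste(bad, collapse = ", "))
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0) stop("sequence contains no unambiguous bases")
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  as.numeric(gc / acgt)
}

# sequences as raw byte vectors for fast vectorized comparison
seq_raw <- function(seq) charToRaw(toupper(seq))

#' Maximum ungapped identity of a window against a reference
#'
#' Slides the window over every equal-length substring of the reference and
#' returns the best fraction of matching positions (matches / window
#' length). This is the identity screen used to require >= 90% nucleotide
#' identity between probe regions and environmental sequences.
#'
#' @param window,reference nucleotide strings; `nchar(window)` must not
#'   exceed `nchar(reference)`.
#' @param both_strands also scan the reverse complement of the reference.
#' @return identity fraction in \[0, 1\].
#' @export
window_identity <- function(window, reference, both_strands = FALSE) {
  w <- seq_raw(window); r <- seq_raw(reference)
  if (length(w) > length(r)) stop("window longer than reference")
  best <- max_identity_at_offsets(w, r, 0:(length(r) - length(w)))
  if (both_strands) {
    rc <- seq_raw(revcomp(rawToChar(r)))
    best <- max(best, max_identity_at_offsets(w, rc,
                                              0:(length(rc) - length(w))))
  }
  best
}

max_identity_at_offsets <- function(w, r, offsets) {
  n <- length(w)
  best <- 0
  for (off in offsets) {
    m <- sum(w == r[(off + 1):(off + n)])
    if (m > best) best <- m
  }
  best / n
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]),
                                 collapse = ""))
}

# anchored identity: candidate alignment offsets are those sharing an exact
# k-mer with the reference. For k = 8 and window lengths <= 318 this is
# exact for any identity >= 0.90: m <= 0.1 L mismatches split the window
# into m + 1 match runs totalling >= 0.9 L, so the longest run has length
# >= 0.9 L / (0.1 L + 1) >= 8, guaranteeing a shared 8-mer at the true
# offset. Identities below the gate may be reported as lower bounds.
anchored_identity <- function(w_raw, window_kmers, r_raw, ref_env,
                              k = 8L, identity_min = 0) {
  n <- length(w_raw)
  if (n < k)
    return(max_identity_at_offsets(w_raw, r_raw, 0:(length(r_raw) - n)))
  hits <- mget(window_kmers, envir = ref_env, ifnotfound = list(NULL))
  lens <- lengths(hits)
  if (sum(lens) == 0) return(0)
  p <- rep.int(seq_along(window_kmers), lens)
  offs <- unlist(hits, use.names = FALSE) - p   # 0-based
  offs <- offs[offs >= 0L & offs <= length(r_raw) - n]
  if (!length(offs)) return(0)
  # any offset at identity t shares at least (k t - (k-1)) n - (k-1)
  # k-mers with the window (match runs of length r contribute r - k + 1),
  # so offsets with fewer shared k-mers cannot reach the gate
  min_support <- max(1L,
                     floor((k * identity_min - (k - 1)) * n - (k - 1)))
  cnt <- table(offs)
  keep <- as.integer(names(cnt)[cnt >= min_support])
  if (!length(keep)) return(0)
  max_identity_at_offsets(w_raw, r_raw, keep)
}

# hashed k-mer -> start positions (1-based) of a reference string
kmer_env <- function(seq, k = 8L) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < k) return(new.env(hash = TRUE))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  sp <- split(starts, kmers)
  list2env(sp, hash = TRUE, size = max(length(sp), 29L))
}

#' Probe design configuration
#'
#' @param length_set window lengths (bp) scanned by
#'   [enumerate_candidates()]; all must lie within `length_bounds`.
#' @param length_bounds admissible probe length range, bp (default 156-318).
#' @param gc_band admissible GC fraction band; the default mirrors the GC
#'   range of the target pelagiphage genomes (22.0-43.2%).
#' @param identity_min minimum ungapped identity against every reference
#'   sequence (default 0.90, the usability threshold for FISH).
#' @param offtarget_max candidates whose identity (or shared-k-mer
#'   fraction, per `offtarget_method`) against any off-target sequence
#'   strictly exceeds this are removed (default 0.80).
#' @param offtarget_method `"identity"` (exact ungapped scan; exact but
#'   quadratic, suited to small off-target sets) or `"kmer"` (fraction of
#'   the candidate's 12-mers present in the off-target set, either strand;
#'   linear-time screen for large sets).
#' @param step window start step in bp.
#' @param k_min,k_max probes per target (default 10-13).
#' @param gene_weights named preference weights for annotated gene classes;
#'   terminases, polymerases and structural genes are preferred as the most
#'   conserved.
#' @param w_gene,w_identity,w_gc score weights in [select_probes()].
#' @return a `probe_config`.
#' @export
probe_config <- function(length_set = c(156L, 200L, 250L, 318L),
                         length_bounds = c(156L, 318L),
                         gc_band = c(0.22, 0.432),
                         identity_min = 0.90,
                         offtarget_max = 0.80,
                         offtarget_method = c("identity", "kmer"),
                         step = 10L,
                         k_min = 10L, k_max = 13L,
                         gene_weights = c(terminase = 2, polymerase = 2,
                                          structural = 2, other = 1,
                                          unannotated = 1),
                         w_gene = 1, w_identity = 1, w_gc = 1) {
  stopifnot(all(length_set >= length_bounds[1]),
            all(length_set <= length_bounds[2]),
            identity_min >= 0, identity_min <= 1,
            offtarget_max >= 0, offtarget_max <= 1,
            step >= 1, k_min >= 1, k_max >= k_min)
  offtarget_method <- match.arg(offtarget_method)
  structure(list(length_set = as.integer(sort(unique(length_set))),
                 length_bounds = as.integer(length_bounds),
                 gc_band = gc_band, identity_min = identity_min,
                 offtarget_max = offtarget_max,
                 offtarget_method = offtarget_method,
                 step = as.integer(step),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 gene_weights = gene_weights, w_gene = w_gene,
                 w_identity = w_identity, w_gc = w_gc),
            class = "probe_config")
}

#' Enumerate candidate probe windows on a target genome
#'
#' Slides windows of each configured length over the genome at the
#' configured step and keeps windows whose GC lies in the configured band
#' and whose minimum ungapped identity against every supplied reference is
#' at least `identity_min`. When a gene annotation table is supplied, a
#' window fully inside an annotated gene inherits its class
#' (terminase / polymerase / structural / other); windows outside genes are
#' `unannotated`.
#'
#' @param genome target genome as a nucleotide string (or named length-1
#'   character vector).
#' @param references character vector of reference/metagenome sequences the
#'   probe regions must match (>= `identity_min`); empty set skips the
#'   identity screen with a warning.
#' @param annotations optional data.frame with columns `start`, `end`
#'   (0-based half-open) and `class`.
#' @param cfg a [probe_config()].
#' @param target_id identifier recorded on the candidates.
#' @return data.frame of candidates: `target_id`, `start`, `end` (0-based
#'   half-open), `length`, `gc`, `min_identity`, `gene_class`, `seq`.
#' @export
enumerate_candidates <- function(genome, references = character(0),
                                 annotations = NULL,
                                 cfg = probe_config(),
                                 target_id = "target") {
  stopifnot(inherits(cfg, "probe_config"))
  g <- toupper(as.character(genome)[1])
  L <- nchar(g)
  if (L < min(cfg$length_set)) stop("genome shorter than the minimum ",
                                    "probe length")
  screen <- length(references) > 0
  if (!screen)
    warning("no reference sequences supplied; identity screen skipped")
  k <- 8L
  gr <- seq_raw(g)
  is_gc <- gr == charToRaw("G") | gr == charToRaw("C")
  is_n <- gr == charToRaw("N")
  cum_gc <- c(0L, cumsum(is_gc))
  cum_n <- c(0L, cumsum(is_n))
  gkmers <- if (L >= k) substring(g, 1:(L - k + 1L), k:L) else character(0)
  refs <- lapply(references, function(r) {
    r <- toupper(r)
    list(raw = seq_raw(r), env = kmer_env(r, k))
  })
  a_start <- integer(0); a_len <- integer(0)
  a_gc <- numeric(0); a_id <- numeric(0)
  for (len in cfg$length_set) {
    if (len > L) next
    starts0 <- seq(0L, L - len, by = cfg$step)   # 0-based
    for (s0 in starts0) {
      n_acgt <- len - (cum_n[s0 + len + 1L] - cum_n[s0 + 1L])
      if (n_acgt == 0) next
      gc <- (cum_gc[s0 + len + 1L] - cum_gc[s0 + 1L]) / n_acgt
      if (gc < cfg$gc_band[1] || gc > cfg$gc_band[2]) next
      min_id <- NA_real_
      if (screen) {
        w <- gr[(s0 + 1L):(s0 + len)]
        wk <- gkmers[(s0 + 1L):(s0 + len - k + 1L)]
        min_id <- 1
        for (rf in refs) {
          id <- anchored_identity(w, wk, rf$raw, rf$env, k,
                                  identity_min = cfg$identity_min)
          if (id < min_id) min_id <- id
          if (min_id < cfg$identity_min) break
        }
        if (min_id < cfg$identity_min) next
      }
      a_start <- c(a_start, s0); a_len <- c(a_len, len)
      a_gc <- c(a_gc, gc); a_id <- c(a_id, min_id)
    }
  }
  if (!length(a_start))
    return(data.frame(target_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      gc = numeric(0), min_identity = numeric(0),
                      gene_class = character(0), seq = character(0)))
  out <- data.frame(
    target_id = target_id, start = a_start, end = a_start + a_len,
    length = a_len, gc = a_gc, min_identity = a_id,
    gene_class = vapply(seq_along(a_start), function(i)
      annotate_window(a_start[i], a_start[i] + a_len[i], annotations),
      character(1)),
    seq = substring(g, a_start + 1, a_start + a_len))
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

annotate_window <- function(start, end, annotations) {
  if (is.null(annotations) || !nrow(annotations)) return("unannotated")
  hit <- annotations$start <= start & annotations$end >= end
  if (!any(hit)) return("unannotated")
  cls <- annotations$class[which(hit)[1]]
  if (cls %in% c("terminase", "polymerase", "structural")) cls else "other"
}

#' Remove candidates with ambiguous similarity to off-target sequences
#'
#' A candidate is removed when its maximum ungapped identity against any
#' off-target sequence (both strands) strictly exceeds `offtarget_max`;
#' candidates exactly at the threshold are retained. Removal reasons are
#' attached as an attribute.
#'
#' @param cands candidate data.frame from [enumerate_candidates()].
#' @param offtarget_db character vector of off-target sequences (empty set
#'   is a no-op).
#' @param cfg a [probe_config()].
#' @return the filtered candidate data.frame, with attribute `removed`
#'   (data.frame of removed candidates and their offending identities).
#' @export
screen_offtargets <- function(cands, offtarget_db = character(0),
                              cfg = probe_config()) {
  if (!nrow(cands) || !length(offtarget_db)) {
    attr(cands, "removed") <- cbind(cands[0, ], offtarget_identity =
                                      numeric(0))
    return(cands)
  }
  off_id <- if ((cfg$offtarget_method %||% "identity") == "kmer") {
    k <- 12L
    env <- new.env(hash = TRUE, size = 2L * sum(nchar(offtarget_db)))
    for (o in offtarget_db) for (s in c(toupper(o), revcomp(o))) {
      n <- nchar(s)
      if (n < k) next
      for (km in unique(substring(s, 1:(n - k + 1L), k:n)))
        assign(km, TRUE, envir = env)
    }
    vapply(cands$seq, function(s) {
      n <- nchar(s)
      if (n < k) return(0)
      kms <- substring(toupper(s), 1:(n - k + 1L), k:n)
      mean(vapply(kms, exists, logical(1), envir = env,
                  inherits = FALSE))
    }, numeric(1))
  } else vapply(cands$seq, function(s) {
    max(vapply(offtarget_db, function(o) {
      if (nchar(s) > nchar(o)) return(0)
      window_identity(s, o, both_strands = TRUE)
    }, numeric(1)))
  }, numeric(1))
  drop <- off_id > cfg$offtarget_max    # strict inequality removes
  removed <- cbind(cands[drop, , drop = FALSE],
                   offtarget_identity = off_id[drop])
  kept <- cands[!drop, , drop = FALSE]
  attr(kept, "removed") <- removed
  kept
}

#' Select a final probe set from screened candidates
#'
#' Greedy selection by descending score
#' `w_gene * gene_weight + w_identity * min_identity +
#'  w_gc * (1 - |gc - genome_gc|)`, subject to pairwise non-overlap and a
#' soft even-spacing constraint (a candidate closer than
#' `genome_length / (2 k_max)` to an already chosen probe is deferred until
#' no other candidate fits). Selection stops at `k_max` probes; fewer than
#' `k_min` surviving candidates is an error. Ties break to the leftmost
#' start, then the shortest window, so selection is deterministic.
#'
#' @param cands screened candidate data.frame.
#' @param cfg a [probe_config()].
#' @param genome_gc GC fraction of the target genome (for the GC-closeness
#'   score term); defaults to the mean candidate GC.
#' @param genome_length target genome length (for the spacing constraint);
#'   defaults to `max(cands$end)`.
#' @return a `probe_set`: list with `target_id`, `probes` (data.frame) and
#'   `summary` (count, mean/sd GC, min identity).
#' @export
select_probes <- function(cands, cfg = probe_config(), genome_gc = NULL,
                          genome_length = NULL) {
  if (nrow(cands) < cfg$k_min)
    stop("only ", nrow(cands), " candidates survive screening but k_min = ",
         cfg$k_min, "; binding constraint: candidate supply")
  genome_gc <- genome_gc %||% mean(cands$gc)
  genome_length <- genome_length %||% max(cands$end)
  gw <- cfg$gene_weights[cands$gene_class]
  gw[is.na(gw)] <- cfg$gene_weights[["other"]]
  id_term <- ifelse(is.na(cands$min_identity), 1, cands$min_identity)
  score <- cfg$w_gene * as.numeric(gw) + cfg$w_identity * id_term +
    cfg$w_gc * (1 - abs(cands$gc - genome_gc))
  ord <- order(-score, cands$start, cands$length)
  min_gap <- genome_length / (2 * cfg$k_max)
  chosen <- integer(0)
  deferred <- integer(0)
  for (i in ord) {
    if (length(chosen) >= cfg$k_max) break
    if (overlaps_any(cands, i, chosen)) next
    ctr <- (cands$start[i] + cands$end[i]) / 2
    if (length(chosen)) {
      ctrs <- (cands$start[chosen] + cands$end[chosen]) / 2
      if (min(abs(ctrs - ctr)) < min_gap) { deferred <- c(deferred, i); next }
    }
    chosen <- c(chosen, i)
  }
  for (i in deferred) {   # spacing is a soft constraint
    if (length(chosen) >= cfg$k_max) break
    if (!overlaps_any(cands, i, chosen)) chosen <- c(chosen, i)
  }
  if (length(chosen) < cfg$k_min)
    stop("only ", length(chosen), " non-overlapping probes selectable but ",
         "k_min = ", cfg$k_min, "; binding constraint: non-overlap")
  probes <- cands[sort(chosen), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(target_id = probes$target_id[1],
                 probes = probes,
                 summary = list(count = nrow(probes),
                                mean_gc = mean(probes$gc),
                                sd_gc = sd(probes$gc),
                                min_identity = suppressWarnings(
                                  min(probes$min_identity, na.rm = TRUE)))),
            class = "probe_set")
}

overlaps_any <- function(cands, i, chosen) {
  if (!length(chosen)) return(FALSE)
  any(cands$start[i] < cands$end[chosen] &
        cands$end[i] > cands$start[chosen])
}

#' @export
print.probe_set <- function(x, ...) {
  s <- x$summary
  cat("probe_set for", x$target_id, "-", s$count, "probes; mean GC",
      sprintf("%.3f +/- %.3f", s$mean_gc, s$sd_gc), "; min identity",
      sprintf("%.3f", s$min_identity), "\n")
  invisible(x)
}

#' Design probes for a target genome end to end
#'
#' Convenience wrapper: [enumerate_candidates()] then
#' [screen_offtargets()] then [select_probes()]. Inputs may be file paths
#' to FASTA (read via Biostrings) or in-memory character vectors.
#'
#' @param genome FASTA path or nucleotide string.
#' @param references FASTA path or character vector (identity screen).
#' @param offtargets FASTA path or character vector (exclusion screen).
#' @param annotations optional gene table (data.frame or TSV path with
#'   columns id, start, end, class; 0-based half-open).
#' @param cfg a [probe_config()].
#' @return a `probe_set`.
#' @export
design_probes <- function(genome, references = character(0),
                          offtargets = character(0), annotations = NULL,
                          cfg = probe_config()) {
  g <- read_seqs(genome)
  refs <- read_seqs(references)
  offs <- read_seqs(offtargets)
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- utils::read.delim(annotations)
  cands <- enumerate_candidates(g[1], refs, annotations, cfg,
                                target_id = names(g)[1] %||% "target")
  cands <- screen_offtargets(cands, offs, cfg)
  select_probes(cands, cfg, genome_gc = gc_fraction(g[1]),
                genome_length = nchar(g[1]))
}

# accept FASTA file paths or plain character vectors of sequences
read_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && !grepl("[^ACGTNacgtn]", x) &&
      nchar(x) > 0) return(stats::setNames(toupper(x), "seq1"))
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  if (!length(x)) return(character(0))
  out <- toupper(as.character(x))
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

#' Write a probe set as TSV, BED and FASTA
#'
#' @param pset a `probe_set`.
#' @param prefix output path prefix; writes `<prefix>.tsv`, `<prefix>.bed`
#'   and `<prefix>.fasta`.
#' @return invisibly, the three paths.
#' @export
write_probe_set <- function(pset, prefix) {
  stopifnot(inherits(pset, "probe_set"))
  p <- pset$probes
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(p[, setdiff(names(p), "seq")], tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- paste0(prefix, ".bed")
  utils::write.table(data.frame(p$target_id, p$start, p$end,
                                paste0("probe_", seq_len(nrow(p)))),
                     bed, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  fa <- paste0(prefix, ".fasta")
  writeLines(as.vector(rbind(paste0(">probe_", seq_len(nrow(p)), "_",
                                    p$target_id, ":", p$start, "-", p$end),
                             p$seq)), fa)
  invisible(c(tsv = tsv, bed = bed, fasta = fa))
}
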