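# Information-theoretic discovery of carbonylation-related motifs and the
# cumulative-information-gain motif predictor built on top of them.
#
# Candidate wildcard patterns are scored by how much class information their
# presence carries on carbonylation-vs-noncarbonylation segment sets. To
# stabilise against the heavy class imbalance, the noncarbonylation side is
# resampled 10 times at the size of the carbonylation set; the information
# gain ratio (IGR) relates the gain under the true labels to the gain under
# a permuted-label null reference.

MAX_PATTERN_LENGTH <- 10L
FREQ_THRESHOLD <- 0.05
IGR_FLOOR <- 1e-6

#' Build a motif discovery corpus
#'
#' `D_cs` is the set of carbonylation-labelled segments; ten
#' noncarbonylation replicates, each of exactly `|D_cs|` segments drawn
#' without replacement, mitigate sampling bias on the (much larger)
#' negative side.
#'
#' @param segments segment data frame with `window` and `label` columns.
#' @param seed integer seed.
#' @param n_replicates number of negative replicates (default 10).
#' @return a `motif_corpus` list with `d_cs` (character windows),
#'   `d_ncs` (list of character vectors) and `seed`.
#' @export
build_corpus <- function(segments, seed = 1L, n_replicates = 10L) {
  pos <- segments$window[segments$label == "carbonylation"]
  neg <- segments$window[segments$label != "carbonylation"]
  if (length(neg) < length(pos)) {
    stop_data("need at least ", length(pos), " noncarbonylation segments, ",
              "have ", length(neg))
  }
  reps <- with_seed(derive_seed(seed, "corpus"), {
    lapply(seq_len(n_replicates), function(tau) {
      neg[sample.int(length(neg), length(pos))]
    })
  })
  structure(list(d_cs = pos, d_ncs = reps, seed = as.integer(seed)),
            class = "motif_corpus")
}

#' Shannon entropy of class counts, in bits
#'
#' @param class_counts nonnegative counts, one per class.
#' @return `-sum(p * log2(p))` over the nonzero classes.
#' @export
entropy_bits <- function(class_counts) {
  if (any(class_counts < 0)) stop_config("counts must be nonnegative")
  total <- sum(class_counts)
  if (total == 0) stop_data("entropy of an empty set is undefined")
  p <- class_counts[class_counts > 0] / total
  -sum(p * log2(p))
}

# wildcard pattern -> regex ('x' matches any of the 20 residues, never the
# terminal padding character 'X')
pattern_regex <- function(pattern) {
  gsub("x", "[ACDEFGHIKLMNPQRSTVWY]", pattern, fixed = TRUE)
}

validate_pattern <- function(pattern, min_len = 4L,
                             max_len = MAX_PATTERN_LENGTH) {
  n <- nchar(pattern)
  if (n < min_len || n > max_len) {
    stop_config("pattern length must lie in [", min_len, ", ", max_len,
                "], got '", pattern, "'")
  }
  chars <- strsplit(pattern, "")[[1]]
  if (chars[1] == "x" || chars[n] == "x") {
    stop_config("patterns may not begin or end with a wildcard: '",
                pattern, "'")
  }
  if (!all(chars %in% c(AA20, "x"))) {
    stop_config("pattern '", pattern, "' contains characters outside the ",
                "residue alphabet plus 'x'")
  }
  invisible(pattern)
}

#' Generate candidate wildcard patterns
#'
#' Two sources are combined and de-duplicated: (i) *mined* candidates —
#' every distinct ungapped k-mer of length 4 to `mine_max_len` occurring in
#' more than `mine_floor` of the supplied positive segments, plus wildcard
#' variants of those k-mers; and (ii) *random* candidates drawn uniformly
#' over the residue alphabet with an interior wildcard probability. Mining
#' guarantees that patterns frequent enough to pass the downstream 5%
#' frequency filter actually enter the candidate pool, which purely random
#' generation cannot ensure at realistic pool sizes.
#'
#' @param n_patterns number of random candidates to draw (the mined
#'   candidates come on top of these).
#' @param length_range integer (min, max) pattern length within [4, 10].
#' @param seed integer seed.
#' @param wildcard_prob probability of replacing each interior position of a
#'   random or mined pattern with the wildcard 'x'.
#' @param mined_from optional character vector of positive segment windows
#'   to mine k-mers from (`NULL` disables mining: fully random mode).
#' @param mine_max_len maximum mined k-mer length (default 6).
#' @param mine_floor minimum fraction of positive segments a k-mer must
#'   occur in to be mined (default `FREQ_THRESHOLD`).
#' @return a character vector of unique patterns.
#' @export
generate_patterns <- function(n_patterns = 500L, length_range = c(4L, 10L),
                              seed = 1L, wildcard_prob = 0.15,
                              mined_from = NULL, mine_max_len = 6L,
                              mine_floor = FREQ_THRESHOLD) {
  if (length_range[1] < 4 || length_range[2] > MAX_PATTERN_LENGTH ||
      length_range[1] > length_range[2]) {
    stop_config("pattern length range must lie within [4, ",
                MAX_PATTERN_LENGTH, "]")
  }
  out <- character(0)
  with_seed(derive_seed(seed, "patterns"), {
    if (!is.null(mined_from) && length(mined_from) > 0) {
      for (k in length_range[1]:min(mine_max_len, length_range[2])) {
        kmers <- unlist(lapply(mined_from, function(wdw) {
          n <- nchar(wdw)
          if (n < k) return(character(0))
          unique(substring(wdw, 1:(n - k + 1), k:n))
        }))
        kmers <- kmers[!grepl(PAD_CHAR, kmers, fixed = TRUE)]
        counts <- table(kmers)
        frequent <- names(counts)[counts > mine_floor * length(mined_from)]
        out <- c(out, frequent)
        # wildcarded variants of the mined cores
        if (wildcard_prob > 0 && k > 2 && length(frequent) > 0) {
          variants <- vapply(frequent, function(pat) {
            ch <- strsplit(pat, "")[[1]]
            interior <- 2:(k - 1)
            flip <- interior[stats::runif(length(interior)) < wildcard_prob]
            ch[flip] <- "x"
            paste(ch, collapse = "")
          }, "")
          out <- c(out, variants)
        }
      }
    }
    if (n_patterns > 0) {
      rand <- vapply(seq_len(n_patterns), function(i) {
        l <- sample(length_range[1]:length_range[2], 1)
        ch <- sample(AA20, l, replace = TRUE)
        if (l > 2 && wildcard_prob > 0) {
          interior <- 2:(l - 1)
          flip <- interior[stats::runif(length(interior)) < wildcard_prob]
          ch[flip] <- "x"
        }
        paste(ch, collapse = "")
      }, "")
      out <- c(out, rand)
    }
  })
  unique(out)
}

#' Fraction of segments containing a pattern
#'
#' Presence/absence semantics: overlapping matches count once per segment.
#'
#' @param pattern a wildcard pattern.
#' @param segment_set character vector of segment windows.
#' @return fraction in [0, 1] (0 for an empty set).
#' @export
pattern_frequency <- function(pattern, segment_set) {
  if (length(segment_set) == 0) return(0)
  mean(grepl(pattern_regex(pattern), segment_set, perl = TRUE))
}

#' Frequency-filter candidate patterns
#'
#' A pattern survives iff its frequency in the carbonylation set strictly
#' exceeds the threshold while its mean frequency across the negative
#' replicates stays strictly below it.
#'
#' @param patterns character vector of candidates.
#' @param corpus a [build_corpus()] result.
#' @param threshold frequency threshold T (default 0.05).
#' @return the surviving patterns, with attributes `f_cs` and `f_ncs_mean`.
#' @export
filter_patterns <- function(patterns, corpus, threshold = FREQ_THRESHOLD) {
  if (threshold <= 0 || threshold >= 1) {
    stop_config("threshold must lie in (0, 1)")
  }
  f_cs <- vapply(patterns, pattern_frequency, 0, corpus$d_cs)
  f_ncs <- vapply(patterns, function(p) {
    mean(vapply(corpus$d_ncs, function(rep) pattern_frequency(p, rep), 0))
  }, 0)
  keep <- f_cs > threshold & f_ncs < threshold
  out <- patterns[keep]
  attr(out, "f_cs") <- unname(f_cs[keep])
  attr(out, "f_ncs_mean") <- unname(f_ncs[keep])
  out
}

#' Information gain of a pattern on a labelled two-class segment set
#'
#' The decision-tree information gain of splitting the set on pattern
#' presence: `IG = H(D) - [f * H(class | present) + (1 - f) * H(class |
#' absent)]`, with `f` the presence fraction. Always nonnegative.
#'
#' @param windows character vector of segment windows.
#' @param labels logical or 0/1 vector (TRUE = carbonylation).
#' @param pattern a wildcard pattern.
#' @return information gain in bits.
#' @export
information_gain <- function(windows, labels, pattern) {
  labels <- as.logical(labels)
  present <- grepl(pattern_regex(pattern), windows, perl = TRUE)
  h0 <- entropy_bits(c(sum(labels), sum(!labels)))
  f <- mean(present)
  h_in <- if (any(present)) {
    entropy_bits(c(sum(labels & present), sum(!labels & present)))
  } else 0
  h_out <- if (any(!present)) {
    entropy_bits(c(sum(labels & !present), sum(!labels & !present)))
  } else 0
  max(h0 - (f * h_in + (1 - f) * h_out), 0)
}

#' Score, rank and select the top motifs
#'
#' For each pattern and each negative replicate, the information gain is
#' computed on the union of the carbonylation set and the replicate under
#' the true labels (`ig_cs`), and on the same union with randomly permuted
#' labels (`ig_ncs`, a null reference), both averaged over the replicates.
#' The information gain ratio `igr = ig_cs / max(ig_ncs, 1e-6)` ranks the
#' patterns; the top `q` are kept and categorised as highly (IGR > 10),
#' moderately (2 <= IGR <= 10) or marginally (1 <= IGR < 2) favoured.
#'
#' @param patterns filtered pattern vector (see [filter_patterns()]).
#' @param corpus a [build_corpus()] result.
#' @param q number of motifs to keep.
#' @return a `motif_model`: data frame `motifs` (pattern, ig_cs,
#'   ig_ncs_mean, igr, category) sorted by igr descending (ties by ig_cs,
#'   then pattern), plus `q` and `seed`.
#' @export
rank_and_select <- function(patterns, corpus, q = 50L) {
  if (length(patterns) == 0) {
    warning("no patterns survived filtering; returning an empty motif model")
    return(structure(list(motifs = data.frame(pattern = character(),
                                              ig_cs = numeric(),
                                              ig_ncs_mean = numeric(),
                                              igr = numeric(),
                                              category = character()),
                          q = q, seed = corpus$seed),
                     class = "motif_model"))
  }
  n_pos <- length(corpus$d_cs)
  n_rep <- length(corpus$d_ncs)
  ig_cs <- ig_ncs <- matrix(0, length(patterns), n_rep)
  for (tau in seq_len(n_rep)) {
    windows <- c(corpus$d_cs, corpus$d_ncs[[tau]])
    labels <- c(rep(TRUE, n_pos), rep(FALSE, length(corpus$d_ncs[[tau]])))
    perm <- with_seed(derive_seed(corpus$seed, "igr-null", tau),
                      sample(labels))
    for (j in seq_along(patterns)) {
      ig_cs[j, tau] <- information_gain(windows, labels, patterns[j])
      ig_ncs[j, tau] <- information_gain(windows, perm, patterns[j])
    }
  }
  ig_cs_mean <- rowMeans(ig_cs)
  ig_ncs_mean <- rowMeans(ig_ncs)
  igr <- ig_cs_mean / pmax(ig_ncs_mean, IGR_FLOOR)
  category <- ifelse(igr > 10, "highly",
              ifelse(igr >= 2, "moderately",
              ifelse(igr >= 1, "marginally", "unfavored")))
  ord <- order(-igr, -ig_cs_mean, patterns)
  keep <- ord[seq_len(min(q, length(ord)))]
  structure(list(motifs = data.frame(pattern = patterns[keep],
                                     ig_cs = ig_cs_mean[keep],
                                     ig_ncs_mean = ig_ncs_mean[keep],
                                     igr = igr[keep],
                                     category = category[keep],
                                     stringsAsFactors = FALSE),
                 q = q, seed = corpus$seed),
            class = "motif_model")
}

#' Discover motifs from a segment table in one call
#'
#' Convenience wrapper: corpus construction, candidate generation (mined +
#' random), frequency filtering and IGR ranking.
#'
#' @param segments segment data frame.
#' @param q number of motifs to keep.
#' @param threshold frequency threshold T.
#' @param n_random number of random candidate patterns.
#' @param length_range candidate length range.
#' @param seed integer seed.
#' @return a `motif_model`.
#' @export
discover_motifs <- function(segments, q = 50L, threshold = FREQ_THRESHOLD,
                            n_random = 500L, length_range = c(4L, 10L),
                            seed = 1L) {
  corpus <- build_corpus(segments, seed = seed)
  patterns <- generate_patterns(n_random, length_range, seed = seed,
                                mined_from = corpus$d_cs)
  survivors <- filter_patterns(patterns, corpus, threshold)
  rank_and_select(survivors, corpus, q)
}

#' Cumulative-IG motif score of a segment
#'
#' The sum of `ig_cs` over the model motifs present in the segment window;
#' 0 when none match. Used as the propensity of the motif-based predictor.
#'
#' @param windows character vector of segment windows.
#' @param model a `motif_model`.
#' @return numeric vector of nonnegative scores.
#' @export
motif_score <- function(windows, model) {
  scores <- numeric(length(windows))
  for (j in seq_len(nrow(model$motifs))) {
    hit <- grepl(pattern_regex(model$motifs$pattern[j]), windows,
                 perl = TRUE)
    scores[hit] <- scores[hit] + model$motifs$ig_cs[j]
  }
  scores
}

#' Write a motif model as TSV
#' @param model a `motif_model`.
#' @param path output path.
#' @export
write_motif_model <- function(model, path) {
  utils::write.table(model$motifs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a motif model written by [write_motif_model()]
#' @param path TSV path.
#' @return a `motif_model`.
#' @export
read_motif_model <- function(path) {
  motifs <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(motifs = motifs, q = nrow(motifs), seed = NA_integer_),
            class = "motif_model")
}
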