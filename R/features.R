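# Feature encoding: segment-level physicochemical matrices, protein-level
# PSSM windows and per-residue embeddings from a pluggable provider.

.physchem_cache <- new.env(parent = emptyenv())

#' Load the 10-property physicochemical indicator table
#'
#' Ten binary residue properties (hydrophilicity, hydrophobicity, tiny,
#' acidity, positively charged, negatively charged, polarity, aromaticity,
#' sulfur content, aliphatic). The residue-to-indicator assignment follows
#' standard biochemical classes and ships as an editable TSV under
#' `inst/extdata`, so an alternative assignment can be swapped in without
#' touching code. The padding character 'X' maps to the zero vector.
#'
#' @param path optional path to an alternative property TSV (first column
#'   `residue`, then 10 binary indicator columns).
#' @return a 21 x 10 numeric matrix with row names A..Y plus 'X'.
#' @export
physchem_table <- function(path = NULL) {
  key <- if (is.null(path)) "default" else path
  if (!is.null(.physchem_cache[[key]])) return(.physchem_cache[[key]])
  if (is.null(path)) {
    path <- system.file("extdata", "physchem_properties.tsv",
                        package = "selcarb", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) != 11) {
    stop_config("property table must have residue + 10 indicator columns")
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$residue
  if (!all(AA20 %in% rownames(m))) {
    stop_config("property table must define all 20 residues")
  }
  m <- rbind(m[AA20, , drop = FALSE],
             matrix(0, 1, 10, dimnames = list(PAD_CHAR, colnames(m))))
  .physchem_cache[[key]] <- m
  m
}

#' Encode a segment window as a (window length) x 10 physicochemical matrix
#'
#' @param window amino-acid string (may contain the padding character 'X').
#' @param table property matrix from [physchem_table()].
#' @return a nchar(window) x 10 binary matrix.
#' @export
encode_physchem <- function(window, table = physchem_table()) {
  chars <- strsplit(window, "")[[1]]
  idx <- match(chars, rownames(table))
  if (anyNA(idx)) {
    stop_data("cannot encode unknown character(s): ",
              paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a PSSM profile from a TSV file
#'
#' Accepts the 20-column log-odds matrix portion of common PSSM dialects:
#' a header row of residue letters is detected and used to reorder columns;
#' otherwise columns are assumed alphabetical by residue letter (or in the
#' order given by `col_order`).
#'
#' @param path TSV path; rows = positions, 20 numeric columns.
#' @param col_order residue letter order of the columns when no header is
#'   present (default alphabetical, i.e. `AA20`).
#' @return an L x 20 matrix with columns ordered A..Y.
#' @export
read_pssm_profile <- function(path, col_order = AA20) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- all(toupper(first) %in% AA20)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 20) {
    stop_data("PSSM file must have exactly 20 columns, got ", ncol(tab))
  }
  m <- as.matrix(tab)
  order_in <- if (has_header) toupper(first) else col_order
  if (!setequal(order_in, AA20)) {
    stop_data("PSSM column order must cover the 20 residue letters")
  }
  m <- m[, match(AA20, order_in), drop = FALSE]
  colnames(m) <- AA20
  m
}

#' Slice a window from a protein-level PSSM profile
#'
#' Rows falling outside the sequence (terminal overhang) are filled with the
#' uniform background row, which in log-odds space is all zeros.
#'
#' @param pssm_profile L x 20 matrix for the whole protein.
#' @param center_pos 1-based centre position.
#' @param window_size odd window length.
#' @param seq_length optional sequence length check against `nrow(pssm_profile)`.
#' @return a window_size x 20 matrix.
#' @export
encode_pssm_window <- function(pssm_profile, center_pos, window_size,
                               seq_length = NULL) {
  if (!is.null(seq_length) && nrow(pssm_profile) != seq_length) {
    stop_data("PSSM profile has ", nrow(pssm_profile),
              " rows but the sequence has ", seq_length, " residues")
  }
  if (window_size %% 2 == 0) stop_config("window_size must be odd")
  L <- nrow(pssm_profile)
  if (center_pos < 1 || center_pos > L) {
    stop_data("centre position ", center_pos, " outside profile of length ", L)
  }
  w <- (window_size - 1) %/% 2
  out <- matrix(0, window_size, 20, dimnames = list(NULL, AA20))
  rows <- (center_pos - w):(center_pos + w)
  inside <- rows >= 1 & rows <= L
  out[inside, ] <- pssm_profile[rows[inside], , drop = FALSE]
  out
}

# ---- embedding providers ----------------------------------------------------

#' Null embedding provider
#'
#' Returns all-zero vectors; lets the predictor run with the embedding
#' channel switched off (the architecture's ablation studies show the
#' embedding channel is the least influential of its inputs, so this is a
#' fully supported operating mode, not a degraded one).
#'
#' @param dim embedding dimension (default 32).
#' @return an `embedding_provider` with fields `name`, `dim`, `embed(sequence)`.
#' @export
null_embedding_provider <- function(dim = 32L) {
  structure(list(name = "null", dim = as.integer(dim),
                 embed = function(sequence) {
                   matrix(0, nchar(sequence), dim)
                 }),
            class = "embedding_provider")
}

#' Synthetic embedding provider
#'
#' Wraps [simulate_embeddings()] so the trainer can consume embeddings
#' through the same interface a real protein-language-model adapter would
#' use.
#'
#' @param config a [simulation_config].
#' @return an `embedding_provider`.
#' @export
synthetic_embedding_provider <- function(config) {
  structure(list(name = "synthetic", dim = config$embedding_dim,
                 embed = function(sequence) {
                   simulate_embeddings(
                     annotated_protein("q", sequence), config)
                 }),
            class = "embedding_provider")
}

#' Embedding provider backed by precomputed per-protein TSV files
#'
#' @param dir directory of `<protein_id>.tsv` matrices (rows = positions).
#' @param dim embedding dimension.
#' @return an `embedding_provider`; its `embed_protein(id, length)` reads the
#'   file for one protein.
#' @export
file_embedding_provider <- function(dir, dim) {
  structure(list(name = "file", dim = as.integer(dim),
                 embed = NULL,
                 embed_protein = function(id, length) {
                   m <- as.matrix(utils::read.delim(
                     file.path(dir, paste0(id, ".tsv"))))
                   if (nrow(m) != length || ncol(m) != dim) {
                     stop_data("embedding file for ", id,
                               " has wrong dimensions")
                   }
                   m
                 }),
            class = "embedding_provider")
}

#' Apply the two-layer embedding reducer
#'
#' The raw provider vector is passed through two affine layers with a ReLU
#' between them, reducing it to 10 dimensions to strip irrelevant variance.
#' During network training the same parameters are updated jointly with the
#' rest of the model; this function applies the current parameters.
#'
#' @param raw_vector numeric vector (or matrix with vectors in rows) of the
#'   provider dimension.
#' @param params list with `W1` (in x hidden), `b1`, `W2` (hidden x 10), `b2`.
#' @param activation hidden-layer nonlinearity (default ReLU); use
#'   `identity` for the linear reducer.
#' @return a length-10 vector (or matrix of rows of length 10).
#' @export
reduce_embedding <- function(raw_vector, params,
                             activation = function(x) pmax(x, 0)) {
  x <- if (is.matrix(raw_vector)) raw_vector else matrix(raw_vector, 1)
  if (ncol(x) != nrow(params$W1)) {
    stop_config("reducer expects input dimension ", nrow(params$W1),
                ", got ", ncol(x))
  }
  h <- activation(sweep(x %*% params$W1, 2, params$b1, "+"))
  out <- sweep(h %*% params$W2, 2, params$b2, "+")
  if (is.matrix(raw_vector)) out else drop(out)
}

# ---- batch feature construction --------------------------------------------

#' Build feature bundles for a segment table
#'
#' Produces the three channels consumed by the network: physicochemical
#' matrices for each segment window, PSSM windows sliced from protein-level
#' profiles, and the centre residue's raw embedding vector. Deterministic:
#' identical segments, profiles and provider give identical bundles.
#'
#' @param segments segment data frame (see [extract_segments()]).
#' @param proteins named list of [annotated_protein] objects.
#' @param pssms named list of L x 20 profiles (or `NULL` to use zero
#'   profiles, i.e. background log-odds everywhere).
#' @param provider an `embedding_provider` (default: zeros).
#' @param window_size odd window size to crop segments and PSSM windows to.
#' @return a list with arrays `physchem` (n x T x 10), `pssm` (n x T x 20),
#'   `embedding` (n x dim), character `labels`, and the segment table.
#' @export
build_feature_bundles <- function(segments, proteins, pssms = NULL,
                                  provider = NULL, window_size = 13L) {
  if (is.null(provider)) provider <- null_embedding_provider()
  segments <- crop_segments(segments, window_size)
  n <- nrow(segments)
  T_ <- window_size
  phys <- array(0, c(n, T_, 10))
  pssm <- array(0, c(n, T_, 20))
  emb <- matrix(0, n, provider$dim)
  tab <- physchem_table()
  emb_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    phys[i, , ] <- encode_physchem(segments$window[i], tab)
    pid <- segments$protein_id[i]
    if (!is.null(pssms) && !is.null(pssms[[pid]])) {
      pssm[i, , ] <- encode_pssm_window(pssms[[pid]], segments$center_pos[i],
                                        T_)
    }
    if (provider$name != "null") {
      if (is.null(emb_cache[[pid]])) {
        p <- proteins[[pid]]
        emb_cache[[pid]] <- if (!is.null(provider$embed_protein)) {
          provider$embed_protein(pid, nchar(p$sequence))
        } else {
          provider$embed(p$sequence)
        }
      }
      emb[i, ] <- emb_cache[[pid]][segments$center_pos[i], ]
    }
  }
  list(physchem = phys, pssm = pssm, embedding = emb,
       labels = segments$label, segments = segments)
}
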