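# Domain types, annotation I/O and sliding-window segment extraction.
#
# Carbonylation is predicted on the four residue types that carry the large
# majority of experimentally observed sites: lysine (K), arginine (R),
# proline (P) and threonine (T). Every K/P/R/T position is a "target residue"
# and carries one of three functional labels; all other positions are inert
# from the predictor's point of view.

NOT_TARGET <- "not_target"

#' Construct an annotated protein
#'
#' @param id protein identifier.
#' @param sequence amino-acid string over the 20-letter alphabet plus 'X'.
#' @param labels optional character vector, one per residue, each one of
#'   `"carbonylation"`, `"ligand"`, `"nonfunctional"` or `"not_target"`.
#'   When omitted, every K/P/R/T position defaults to `"nonfunctional"` and
#'   every other position to `"not_target"`.
#' @return an object of class `annotated_protein` with fields `id`,
#'   `sequence` and `labels`.
#' @export
annotated_protein <- function(id, sequence, labels = NULL) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c(AA20, PAD_CHAR))
  if (length(bad) > 0) {
    stop_data("protein ", id, ": unknown residue letter(s) ",
              paste(bad, collapse = ", "))
  }
  if (is.null(labels)) {
    labels <- ifelse(chars %in% TARGET_RESIDUES, "nonfunctional", NOT_TARGET)
  }
  if (length(labels) != length(chars)) {
    stop_data("protein ", id, ": labels length ", length(labels),
              " != sequence length ", length(chars))
  }
  is_target <- chars %in% TARGET_RESIDUES
  if (any(labels[!is_target] != NOT_TARGET)) {
    stop_data("protein ", id, ": functional label on a non-K/P/R/T residue")
  }
  if (any(labels[is_target] == NOT_TARGET)) {
    labels[is_target & labels == NOT_TARGET] <- "nonfunctional"
  }
  structure(list(id = id, sequence = sequence, labels = labels),
            class = "annotated_protein")
}

#' @export
print.annotated_protein <- function(x, ...) {
  n_site <- sum(x$labels == "carbonylation")
  n_lig <- sum(x$labels == "ligand")
  cat(sprintf("<annotated_protein %s: %d aa, %d carbonylation, %d ligand>\n",
              x$id, nchar(x$sequence), n_site, n_lig))
  invisible(x)
}

#' Read protein sequences and per-residue functional annotations
#'
#' Sequences come from a FASTA file; annotations from a tab-separated file
#' with header `protein_id  position  residue  label`, positions 1-based.
#' Target residues (K/P/R/T) without an annotation row default to
#' `"nonfunctional"`; non-target residues are labelled `"not_target"`.
#'
#' @param fasta_path path to a FASTA file of amino-acid sequences.
#' @param annotation_path path to the annotation TSV, or `NULL` for no
#'   annotations (all target residues nonfunctional).
#' @return a named list of [annotated_protein] objects.
#' @export
read_annotations <- function(fasta_path, annotation_path = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  proteins <- lapply(seq_along(seqs), function(i) {
    annotated_protein(ids[i], as.character(seqs[[i]]))
  })
  names(proteins) <- ids

  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    required <- c("protein_id", "position", "residue", "label")
    if (!all(required %in% names(ann))) {
      stop_data("annotation file must have columns: ",
                paste(required, collapse = ", "))
    }
    for (k in seq_len(nrow(ann))) {
      pid <- ann$protein_id[k]
      pos <- ann$position[k]
      if (!pid %in% names(proteins)) {
        stop_data("annotation for unknown protein '", pid, "'")
      }
      p <- proteins[[pid]]
      if (pos < 1 || pos > nchar(p$sequence)) {
        stop_data("malformed annotation: protein ", pid, " position ", pos,
                  " outside sequence of length ", nchar(p$sequence))
      }
      res <- substr(p$sequence, pos, pos)
      if (res != toupper(ann$residue[k])) {
        stop_data("annotation/sequence mismatch: protein ", pid,
                  " position ", pos, " is ", res, " in the sequence but ",
                  ann$residue[k], " in the annotation")
      }
      lab <- tolower(ann$label[k])
      if (!lab %in% LABEL_LEVELS) {
        stop_data("unknown label '", ann$label[k], "' for protein ", pid)
      }
      if (!res %in% TARGET_RESIDUES) {
        stop_data("annotation on non-target residue ", res, " (protein ",
                  pid, ", position ", pos, ")")
      }
      proteins[[pid]]$labels[pos] <- lab
    }
  }
  proteins
}

#' Write annotations for a set of proteins
#'
#' Emits one row per annotated (non-default) target residue in the TSV
#' dialect read by [read_annotations()]. Nonfunctional rows are written too,
#' so a write/read round trip reproduces the label vectors exactly.
#'
#' @param proteins list of [annotated_protein] objects.
#' @param path output TSV path.
#' @export
write_annotations <- function(proteins, path) {
  rows <- lapply(proteins, function(p) {
    chars <- strsplit(p$sequence, "")[[1]]
    idx <- which(p$labels != NOT_TARGET)
    if (length(idx) == 0) return(NULL)
    data.frame(protein_id = p$id, position = idx, residue = chars[idx],
               label = p$labels[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write protein sequences as FASTA
#' @param proteins list of [annotated_protein] objects.
#' @param path output path.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(set) <- vapply(proteins, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract fixed-length segments centred on target residues
#'
#' One segment is produced for every occurrence of `residue_type` in the
#' protein, following the sliding-window scheme standard in PTM site
#' prediction: a window of odd length `window_size` centred on the site,
#' padded at the sequence termini with the neutral character 'X'. The
#' default of 27 residues matches the widest window the downstream feature
#' encoders use; narrower windows are obtained by cropping at feature time,
#' so a single extraction serves every window-size configuration.
#'
#' @param protein an [annotated_protein].
#' @param residue_type one of "K", "P", "R", "T".
#' @param window_size odd integer >= 5 (default 27).
#' @return a data frame with columns `protein_id`, `center_pos`,
#'   `residue_type`, `window`, `label`, `pad_count`.
#' @export
extract_segments <- function(protein, residue_type = "K", window_size = 27L) {
  if (window_size %% 2 == 0 || window_size < 5) {
    stop_config("window_size must be an odd integer >= 5, got ", window_size)
  }
  residue_type <- match.arg(residue_type, TARGET_RESIDUES)
  chars <- strsplit(protein$sequence, "")[[1]]
  centers <- which(chars == residue_type)
  if (length(centers) == 0) {
    return(data.frame(protein_id = character(), center_pos = integer(),
                      residue_type = character(), window = character(),
                      label = character(), pad_count = integer(),
                      stringsAsFactors = FALSE))
  }
  w <- (window_size - 1L) %/% 2L
  L <- length(chars)
  windows <- character(length(centers))
  pads <- integer(length(centers))
  for (i in seq_along(centers)) {
    c0 <- centers[i]
    lo <- c0 - w
    hi <- c0 + w
    left_pad <- max(0L, 1L - lo)
    right_pad <- max(0L, hi - L)
    core <- chars[max(1L, lo):min(L, hi)]
    windows[i] <- paste0(strrep(PAD_CHAR, left_pad),
                         paste(core, collapse = ""),
                         strrep(PAD_CHAR, right_pad))
    pads[i] <- left_pad + right_pad
  }
  data.frame(protein_id = protein$id, center_pos = centers,
             residue_type = residue_type, window = windows,
             label = protein$labels[centers], pad_count = pads,
             stringsAsFactors = FALSE)
}

#' Extract segments for every protein in a set
#' @param proteins list of [annotated_protein] objects.
#' @inheritParams extract_segments
#' @return one combined segment data frame.
#' @export
extract_all_segments <- function(proteins, residue_type = "K",
                                 window_size = 27L) {
  do.call(rbind, lapply(proteins, extract_segments,
                        residue_type = residue_type,
                        window_size = window_size))
}

#' Crop segment windows to a narrower (odd) size
#'
#' @param segments segment data frame (windows of odd length).
#' @param window_size odd target size, at most the stored window length.
#' @return the segment data frame with cropped `window` strings and
#'   recomputed `pad_count`.
#' @export
crop_segments <- function(segments, window_size) {
  if (nrow(segments) == 0) return(segments)
  stored <- nchar(segments$window[1])
  if (window_size %% 2 == 0 || window_size > stored) {
    stop_config("window_size must be odd and <= stored size ", stored)
  }
  off <- (stored - window_size) %/% 2
  segments$window <- substr(segments$window, off + 1L, off + window_size)
  segments$pad_count <- vapply(strsplit(segments$window, ""),
                               function(ch) sum(ch == PAD_CHAR), 0L)
  segments
}

#' Stratified train/validation(/test) split of a segment table
#'
#' Splitting is stratified by class label so that each part preserves the
#' class proportions to within one segment per class, mirroring the 80/20
#' train/validation protocol used to fit and tune the predictor.
#'
#' @param segments segment data frame.
#' @param fractions numeric vector summing to 1 (e.g. `c(train = .8,
#'   validation = .2)`); unnamed fractions are named split1, split2, ...
#' @param seed integer seed; the split is deterministic given the seed.
#' @return a named list of segment data frames plus attribute `seed`.
#' @export
split_dataset <- function(segments, fractions = c(train = 0.8,
                                                  validation = 0.2),
                          seed = 1L) {
  if (any(fractions <= 0) || any(fractions >= 1)) {
    stop_config("every split fraction must lie strictly in (0, 1)")
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop_config("split fractions must sum to 1")
  }
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("split", seq_along(fractions))
  }
  n_parts <- length(fractions)
  assignment <- integer(nrow(segments))
  with_seed(derive_seed(seed, "split"), {
    for (lab in unique(segments$label)) {
      idx <- which(segments$label == lab)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      # largest-remainder apportionment keeps each class within +/- 1
      quota <- fractions * n
      base <- floor(quota)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      bounds <- cumsum(c(0, base))
      for (k in seq_len(n_parts)) {
        if (base[k] > 0) {
          assignment[idx[(bounds[k] + 1):bounds[k + 1]]] <- k
        }
      }
    }
  })
  out <- lapply(seq_len(n_parts), function(k) segments[assignment == k, ,
                                                       drop = FALSE])
  names(out) <- names(fractions)
  attr(out, "seed") <- seed
  out
}

#' Write a segment table as TSV
#' @param segments segment data frame.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#' @param path TSV path.
#' @return segment data frame.
#' @export
read_segments <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
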