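# Seeded generator of annotated proteins, PSSM profiles and embedding
# stand-ins. The generator reproduces the statistical structure the method
# assumes: K/P/R/T target residues at roughly 2% carbonylation / 5%
# ligand / 93% nonfunctional, carbonylation neighbourhoods enriched for
# short planted motifs, ligand neighbourhoods with a distinct aromatic
# compositional bias that shares part of the motif vocabulary (so the two
# positive classes are separable but confusable, which is what makes
# cross-prediction observable in synthetic tests).

#' Simulation configuration
#'
#' @param n_proteins number of proteins to generate.
#' @param length_range integer (min, max) protein length in residues.
#' @param class_props proportions (carbonylation, ligand, nonfunctional)
#'   over target residues; must sum to 1. Defaults mirror the class balance
#'   of curated carbonylation benchmarks (about 2% sites, 5% ligand
#'   interaction sites, 93% nonfunctional K residues).
#' @param planted_motifs character vector of wildcard patterns ('x' = any
#'   residue) planted next to carbonylation sites.
#' @param plant_prob probability that a carbonylation site receives a
#'   planted motif.
#' @param motif_share fraction of `plant_prob` at which ligand sites also
#'   receive a planted motif (the cross-prediction confounder).
#' @param ligand_aromatic_rate probability that each residue within
#'   `ligand_halo` of a ligand site is rewritten to an aromatic residue
#'   (F/W/Y), giving ligand sites their own compositional signature.
#' @param ligand_halo half-width of the ligand compositional neighbourhood.
#' @param background residue sampling probabilities (length 20, ordered as
#'   `AA20`); default uniform.
#' @param pssm_sharpness mixing weight in (0, 1] of the true-residue one-hot
#'   against the background in synthetic PSSM rows.
#' @param pssm_noise standard deviation of Gaussian noise added to PSSM
#'   probability rows before the log-odds transform.
#' @param embedding_dim dimension of synthetic residue embeddings.
#' @param embedding_noise scale of smoothed positional noise added to
#'   embeddings.
#' @param seed master integer seed; all randomness in the generator derives
#'   from it through labelled sub-streams.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 50L,
                              length_range = c(200L, 400L),
                              class_props = c(carbonylation = 0.02,
                                              ligand = 0.05,
                                              nonfunctional = 0.93),
                              planted_motifs = c("LRTG", "RKME", "QTAL"),
                              plant_prob = 0.5,
                              motif_share = 0.3,
                              ligand_aromatic_rate = 0.3,
                              ligand_halo = 5L,
                              background = NULL,
                              pssm_sharpness = 0.7,
                              pssm_noise = 0.05,
                              embedding_dim = 32L,
                              embedding_noise = 0.1,
                              seed = 1L) {
  if (abs(sum(class_props) - 1) > 1e-8 || any(class_props < 0)) {
    stop_config("class_props must be nonnegative and sum to 1")
  }
  if (plant_prob < 0 || plant_prob > 1) {
    stop_config("plant_prob must lie in [0, 1]")
  }
  if (plant_prob > 0 && length(planted_motifs) == 0) {
    stop_config("nonzero plant_prob requires at least one planted motif")
  }
  if (pssm_sharpness <= 0 || pssm_sharpness > 1) {
    stop_config("pssm_sharpness must lie in (0, 1]")
  }
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-8) {
    stop_config("background must be 20 probabilities summing to 1")
  }
  names(class_props) <- LABEL_LEVELS
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 class_props = class_props,
                 planted_motifs = toupper(planted_motifs),
                 plant_prob = plant_prob,
                 motif_share = motif_share,
                 ligand_aromatic_rate = ligand_aromatic_rate,
                 ligand_halo = as.integer(ligand_halo),
                 background = background,
                 pssm_sharpness = pssm_sharpness,
                 pssm_noise = pssm_noise,
                 embedding_dim = as.integer(embedding_dim),
                 embedding_noise = embedding_noise,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# instantiate wildcard positions of a planted motif with random residues
instantiate_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  wc <- chars == "x" | chars == "X"
  chars[wc] <- sample(AA20, sum(wc), replace = TRUE)
  chars
}

#' Simulate annotated proteins
#'
#' Sequences are drawn i.i.d. from the background distribution; each K/P/R/T
#' position draws a functional class from `class_props`. Carbonylation sites
#' then receive a planted motif immediately adjacent to the site (left or
#' right, at random) with probability `plant_prob`; ligand sites receive an
#' aromatic compositional bias in their `ligand_halo` neighbourhood and share
#' the motif vocabulary at rate `plant_prob * motif_share`. Assigned
#' carbonylation/ligand centre residues are never overwritten by any edit;
#' target residues created by the edits are labelled nonfunctional.
#'
#' @param config a [simulation_config].
#' @return a named list of [annotated_protein] objects.
#' @export
simulate_proteins <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  proteins <- vector("list", config$n_proteins)
  aromatics <- c("F", "W", "Y")
  for (j in seq_len(config$n_proteins)) {
    proteins[[j]] <- with_seed(derive_seed(config$seed, "protein", j), {
      L <- sample(config$length_range[1]:config$length_range[2], 1)
      chars <- sample(AA20, L, replace = TRUE, prob = config$background)
      targets <- which(chars %in% TARGET_RESIDUES)
      classes <- sample(LABEL_LEVELS, length(targets), replace = TRUE,
                        prob = config$class_props)
      protected <- targets[classes != "nonfunctional"]
      # ligand compositional halo (aromatics only: F/W/Y are never targets,
      # so the halo cannot spawn spurious target residues)
      for (pos in targets[classes == "ligand"]) {
        halo <- setdiff(max(1, pos - config$ligand_halo):
                        min(L, pos + config$ligand_halo), protected)
        rewrite <- halo[stats::runif(length(halo)) <
                          config$ligand_aromatic_rate]
        if (length(rewrite) > 0) {
          chars[rewrite] <- sample(aromatics, length(rewrite), replace = TRUE)
        }
      }
      # motif planting, flush against the centre so that any window of
      # half-width >= motif length fully contains the motif; spans already
      # planted are protected so a later site cannot corrupt an earlier
      # motif, and both sides are tried before giving up
      planted_spans <- integer(0)
      plant_at <- function(pos, prob) {
        if (stats::runif(1) >= prob) return(invisible(NULL))
        motif <- instantiate_motif(sample(config$planted_motifs, 1))
        l <- length(motif)
        sides <- sample(c(-1, 1))
        for (side in sides) {
          span <- if (side < 0) (pos - l):(pos - 1) else (pos + 1):(pos + l)
          if (span[1] < 1 || span[l] > L) next
          if (any(span %in% protected) || any(span %in% planted_spans)) next
          chars[span] <<- motif
          planted_spans <<- c(planted_spans, span)
          return(invisible(NULL))
        }
        invisible(NULL)
      }
      if (config$plant_prob > 0 && length(config$planted_motifs) > 0) {
        for (pos in targets[classes == "carbonylation"]) {
          plant_at(pos, config$plant_prob)
        }
        for (pos in targets[classes == "ligand"]) {
          plant_at(pos, config$plant_prob * config$motif_share)
        }
      }
      # final labels: surviving assigned centres keep their class, all other
      # target residues (including ones the edits created) are nonfunctional
      labels <- rep(NOT_TARGET, L)
      labels[chars %in% TARGET_RESIDUES] <- "nonfunctional"
      keep <- chars[targets] %in% TARGET_RESIDUES
      labels[targets[keep]] <- classes[keep]
      annotated_protein(sprintf("SYN%04d", j), paste(chars, collapse = ""),
                        labels)
    })
  }
  names(proteins) <- vapply(proteins, `[[`, "", "id")
  proteins
}

#' Simulate a PSSM profile for one protein
#'
#' Each row is a sharpened one-hot of the true residue mixed with the
#' background distribution, perturbed with Gaussian noise, renormalised and
#' log2-odds transformed against the background. With sharpness 1 and zero
#' noise the row argmax equals the sequence residue; with sharpness 0 and
#' zero noise every row equals the (all-zero) background log-odds row.
#'
#' @param protein an [annotated_protein].
#' @param config a [simulation_config].
#' @return an L x 20 numeric matrix, columns named by residue letter.
#' @export
simulate_pssm <- function(protein, config) {
  chars <- strsplit(protein$sequence, "")[[1]]
  L <- length(chars)
  bg <- config$background
  with_seed(derive_seed(config$seed, "pssm", protein$id), {
    onehot <- matrix(0, L, 20, dimnames = list(NULL, AA20))
    known <- chars %in% AA20
    onehot[cbind(which(known), match(chars[known], AA20))] <- 1
    # 'X' rows fall back to pure background
    p <- config$pssm_sharpness * onehot +
      (1 - config$pssm_sharpness) * matrix(bg, L, 20, byrow = TRUE)
    if (any(!known)) {
      p[!known, ] <- matrix(bg, sum(!known), 20, byrow = TRUE)
    }
    if (config$pssm_noise > 0) {
      p <- p + matrix(stats::rnorm(L * 20, sd = config$pssm_noise), L, 20)
    }
    p <- pmax(p, 1e-4)
    p <- p / rowSums(p)
    log2(p / matrix(bg, L, 20, byrow = TRUE))
  })
}

# fixed random projection shared by all proteins of a config: one-hot of the
# centred 3-mer (21 letters x 3 slots) -> embedding_dim
embedding_projection <- function(config) {
  alphabet <- c(AA20, PAD_CHAR)
  with_seed(derive_seed(config$seed, "embedding-projection"), {
    matrix(stats::rnorm(config$embedding_dim * 3 * length(alphabet)),
           config$embedding_dim, 3 * length(alphabet)) /
      sqrt(3 * length(alphabet))
  })
}

#' Simulate per-residue embeddings
#'
#' A language-model stand-in: each residue's vector is a fixed random
#' projection (shared across proteins generated under the same seed) of the
#' one-hot encoding of its centred 3-mer, plus smoothed positional noise.
#' Identical 3-mers therefore map to near-identical vectors, giving the
#' embeddings genuine (if shallow) contextual structure.
#'
#' @param protein an [annotated_protein].
#' @param config a [simulation_config].
#' @return an L x embedding_dim numeric matrix.
#' @export
simulate_embeddings <- function(protein, config) {
  if (config$embedding_dim < 1) stop_config("embedding_dim must be >= 1")
  chars <- strsplit(protein$sequence, "")[[1]]
  L <- length(chars)
  alphabet <- c(AA20, PAD_CHAR)
  W <- embedding_projection(config)
  padded <- c(PAD_CHAR, chars, PAD_CHAR)
  onehot <- matrix(0, L, 3 * length(alphabet))
  for (slot in 0:2) {
    letters_at <- padded[seq_len(L) + slot]
    onehot[cbind(seq_len(L),
                 slot * length(alphabet) + match(letters_at, alphabet))] <- 1
  }
  E <- onehot %*% t(W)
  if (config$embedding_noise > 0) {
    E <- E + with_seed(derive_seed(config$seed, "embedding", protein$id), {
      raw <- matrix(stats::rnorm(L * config$embedding_dim,
                                 sd = config$embedding_noise),
                    L, config$embedding_dim)
      # smooth along the sequence so noise is positionally correlated
      if (L >= 3) (raw + rbind(raw[1, ], raw[-L, ]) +
                     rbind(raw[-1, ], raw[L, ])) / 3 else raw
    })
  }
  E
}

#' Write a complete simulated dataset to disk
#'
#' Emits FASTA sequences, the annotation TSV, one PSSM TSV per protein, one
#' embedding TSV per protein, and a manifest JSON recording the
#' configuration and seed so the run can be reproduced bit for bit.
#'
#' @param config a [simulation_config].
#' @param dir output directory (created if missing).
#' @param pssm write PSSM profiles (logical).
#' @param embeddings write embedding matrices (logical).
#' @return invisibly, the list of generated proteins.
#' @export
write_simulated_dataset <- function(config, dir, pssm = TRUE,
                                    embeddings = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- simulate_proteins(config)
  write_fasta(proteins, file.path(dir, "proteins.fasta"))
  write_annotations(proteins, file.path(dir, "annotations.tsv"))
  if (pssm) {
    pdir <- file.path(dir, "pssm")
    dir.create(pdir, showWarnings = FALSE)
    for (p in proteins) {
      m <- simulate_pssm(p, config)
      utils::write.table(round(m, 4), file.path(pdir, paste0(p$id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (embeddings) {
    edir <- file.path(dir, "embeddings")
    dir.create(edir, showWarnings = FALSE)
    for (p in proteins) {
      m <- simulate_embeddings(p, config)
      utils::write.table(round(m, 5), file.path(edir, paste0(p$id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- unclass(config)
  manifest$generated <- length(proteins)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(proteins)
}
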