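# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' All stochastic stages draw their own seed from a single master seed via a
#' fixed integer mixing function, so that subsets of a run (e.g. the PSSM of
#' one protein) are reproducible independently of everything generated before
#' them.
#'
#' @param seed master integer seed.
#' @param ... one or more integer/character stream labels.
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- list(...)
  h <- as.double(seed) %% 2147483647
  for (lab in labels) {
    if (is.character(lab)) {
      lab <- sum(utf8ToInt(lab) * seq_along(utf8ToInt(lab)))
    }
    # 32-bit-safe multiplicative mix (all arithmetic on doubles < 2^53)
    h <- (h * 48271 + as.double(lab) * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

#' Evaluate an expression under a local RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# condition constructors: distinct classes so callers (and the CLI) can map
# failures to exit codes
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("selcarb_config_error", "error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("selcarb_data_error", "error")))
}
stop_training <- function(msg, trajectory = NULL) {
  stop(errorCondition(msg, trajectory = trajectory,
                      class = c("selcarb_training_error", "error")))
}

#' Clamp probabilities away from 0/1 before taking logs
#' @keywords internal
clamp_prob <- function(p, eps = 1e-7) {
  pmin(pmax(p, eps), 1 - eps)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
TARGET_RESIDUES <- c("K", "P", "R", "T")
PAD_CHAR <- "X"

LABEL_LEVELS <- c("carbonylation", "ligand", "nonfunctional")

# ---- parameter-tree utilities (nested lists of numeric arrays) -------------

#' Apply a function to every leaf array of a parameter tree
#' @keywords internal
tree_map <- function(f, tree, ...) {
  rest <- list(...)
  if (is.list(tree)) {
    out <- vector("list", length(tree))
    names(out) <- names(tree)
    for (i in seq_along(tree)) {
      out[[i]] <- do.call(tree_map, c(list(f, tree[[i]]),
                                      lapply(rest, function(r) r[[i]])))
    }
    out
  } else {
    do.call(f, c(list(tree), rest))
  }
}

#' Zero-filled copy of a parameter tree
#' @keywords internal
tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

#' Flatten all leaves of a parameter tree into one numeric vector
#' @keywords internal
tree_flatten <- function(tree) {
  if (is.list(tree)) {
    unlist(lapply(tree, tree_flatten), use.names = FALSE)
  } else {
    as.numeric(tree)
  }
}

#' Rebuild a parameter tree from a flat vector (inverse of tree_flatten)
#' @keywords internal
tree_unflatten <- function(tree, values) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) {
      out <- lapply(node, rebuild)
      names(out) <- names(node)
      out
    } else {
      n <- length(node)
      leaf <- node
      leaf[] <- values[(pos + 1L):(pos + n)]
      pos <<- pos + n
      leaf
    }
  }
  out <- rebuild(tree)
  stopifnot(pos == length(values))
  out
}
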