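.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_aa <- function(n) paste(sample(.aa20, n, replace = TRUE), collapse = "")

# n distinct permutations of a letter multiset, as strings; resamples the
# letters if the multiset is too degenerate to permute n ways.
.distinct_permutations <- function(letters, n) {
  for (attempt in 1:100) {
    out <- unique(vapply(seq_len(n * 20L),
                         function(i) paste(sample(letters), collapse = ""),
                         character(1)))
    if (length(out) >= n) return(out[seq_len(n)])
    letters <- sample(.aa20, length(letters), replace = TRUE)
  }
  abort("Could not generate enough distinct permutations.")
}

#' Specification of a synthetic protein family
#'
#' Describes a planted-motif family used to exercise the full pipeline
#' without external data. Each sequence of a class is a random flank, a
#' domain, and a second random flank. The domain imitates the
#' conservation structure of a real protein family:
#'
#' * a conserved four-residue terminal cap at each end (domain
#'   boundaries of real families are anchored by conserved elements);
#' * a body that alternates conserved blocks (6--12 residues, shared
#'   across the class up to the within-class `divergence` rate, like
#'   conserved secondary-structure elements) with variable blocks (2--5
#'   residues, redrawn uniformly per sequence, like loops);
#' * the class-specific motif overwritten at a random interior offset
#'   (never touching the caps), with substitution noise applied to the
#'   motif positions at the stated rate.
#'
#' Classes are composition-balanced: the caps, the conserved body
#' letters, and the generated motifs of the different classes are
#' distinct *permutations of shared letter multisets*, so no class can
#' be recognized from amino-acid composition alone — the class signal
#' lives entirely in residue arrangement, as it does for the contextual
#' embeddings of real protein families. This is also what makes the
#' reshuffle null sequences (which preserve composition exactly)
#' genuinely out-of-distribution. Flank residues are drawn i.i.d. from
#' the uniform 20-letter distribution; background composition is not the
#' tested signal.
#'
#' @param n_classes Number of classes (>= 2).
#' @param motifs Optional character vector of class motifs (lengths
#'   5--12, pairwise distinct); generated from `seed` when `NULL`.
#' @param motif_length Length of generated motifs (default 9).
#' @param domain_length Two-element range of domain lengths (default
#'   40--50).
#' @param flank_length Two-element range of flank lengths on each side
#'   (default 8--40).
#' @param noise Per-motif-position substitution rate; must lie in
#'   `[0, 0.5)`.
#' @param divergence Within-class substitution rate applied per sequence
#'   to the conserved body positions (not the caps or the motif),
#'   emulating evolutionary divergence among family members; must lie in
#'   `[0, 0.5)` (default 0.1).
#' @param n_per_class Sequences generated per class (default 200).
#' @param seed Integer seed making the family fully reproducible.
#' @return A list of class `spin_family_spec`.
#' @export
family_spec <- function(n_classes = 2L, motifs = NULL, motif_length = 9L,
                        domain_length = c(40L, 50L),
                        flank_length = c(8L, 40L), noise = 0.05,
                        divergence = 0.1, n_per_class = 200L, seed = 1L) {
  if (n_classes < 2L) abort("Need at least 2 classes.")
  if (noise < 0 || noise >= 0.5) abort("`noise` must lie in [0, 0.5).")
  if (divergence < 0 || divergence >= 0.5) {
    abort("`divergence` must lie in [0, 0.5).")
  }
  if (is.null(motifs)) {
    if (motif_length < 5L || motif_length > 12L) {
      abort("`motif_length` must be between 5 and 12.")
    }
    motifs <- withr::with_seed(
      seed, .distinct_permutations(sample(.aa20, motif_length, replace = TRUE),
                                   n_classes)
    )
  }
  if (length(motifs) != n_classes || anyDuplicated(motifs) > 0L) {
    abort("`motifs` must supply one distinct motif per class.")
  }
  if (any(nchar(motifs) < 5L | nchar(motifs) > 12L)) {
    abort("Motif lengths must be between 5 and 12.")
  }
  cap <- 4L
  if (domain_length[1] < max(nchar(motifs)) + 2L * cap) {
    abort(sprintf(
      "Infeasible lengths: the minimum domain length (%d) must cover the longest motif plus the two %d-residue terminal caps.",
      domain_length[1], cap
    ), class = "spinr_spec_error")
  }
  if (flank_length[1] < 1L) abort("Flank lengths must be at least 1.")
  structure(
    list(
      n_classes = as.integer(n_classes), motifs = motifs,
      domain_length = as.integer(domain_length),
      flank_length = as.integer(flank_length), noise = noise,
      divergence = divergence,
      n_per_class = as.integer(n_per_class), cap = cap,
      seed = as.integer(seed)
    ),
    class = "spin_family_spec"
  )
}

#' Generate a labeled synthetic family
#'
#' Builds `n_per_class` sequences per class: random flank, domain
#' (conserved terminal caps, blockwise-conserved body, the class motif
#' noised position-wise at the stated rate and planted at a random
#' interior offset), random flank. The `start`/`end` columns record the
#' true domain coordinates, 1-based inclusive. Identical specs yield
#' identical tibbles.
#'
#' @param spec A [family_spec()].
#' @return A tibble with columns `id`, `sequence`, `start`, `end`,
#'   `label` — the training-table dialect used throughout the package.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "spin_family_spec"))
  cap <- spec$cap
  cons_block <- c(6L, 12L)
  var_block <- c(2L, 5L)
  withr::with_seed(spec$seed + 1L, {
    # caps and conserved body letters: one shared multiset each, one
    # distinct arrangement per class (composition balance across classes)
    start_caps <- .distinct_permutations(sample(.aa20, cap, replace = TRUE),
                                         spec$n_classes)
    end_caps <- .distinct_permutations(sample(.aa20, cap, replace = TRUE),
                                       spec$n_classes)
    body_max <- spec$domain_length[2] - 2L * cap
    mask <- logical(0)
    conserved <- TRUE
    while (length(mask) < body_max) {
      len <- if (conserved) sample(cons_block[1]:cons_block[2], 1L) else
        sample(var_block[1]:var_block[2], 1L)
      mask <- c(mask, rep(conserved, len))
      conserved <- !conserved
    }
    mask <- mask[seq_len(body_max)]
    cons_idx <- which(mask)
    cons_pool <- sample(.aa20, length(cons_idx), replace = TRUE)
    cons_arrangement <- lapply(
      strsplit(.distinct_permutations(cons_pool, spec$n_classes), ""),
      identity
    )
    rows <- purrr::map_dfr(seq_len(spec$n_classes), function(ci) {
      motif <- strsplit(spec$motifs[ci], "")[[1]]
      mlen <- length(motif)
      purrr::map_dfr(seq_len(spec$n_per_class), function(si) {
        dl <- sample(spec$domain_length[1]:spec$domain_length[2], 1L)
        blen <- dl - 2L * cap
        body <- sample(.aa20, blen, replace = TRUE)
        keep <- cons_idx[cons_idx <= blen]
        cons_letters <- cons_arrangement[[ci]][seq_along(keep)]
        diverged <- runif(length(keep)) < spec$divergence
        if (any(diverged)) {
          cons_letters[diverged] <- vapply(
            cons_letters[diverged],
            function(a) sample(setdiff(.aa20, a), 1L), character(1))
        }
        body[keep] <- cons_letters
        dom <- c(strsplit(start_caps[ci], "")[[1]], body,
                 strsplit(end_caps[ci], "")[[1]])
        off <- sample((cap + 1L):(dl - cap - mlen + 1L), 1L)
        planted <- motif
        noisy <- runif(mlen) < spec$noise
        if (any(noisy)) {
          planted[noisy] <- vapply(planted[noisy],
                                   function(a) sample(setdiff(.aa20, a), 1L),
                                   character(1))
        }
        dom[off:(off + mlen - 1L)] <- planted
        lf <- sample(spec$flank_length[1]:spec$flank_length[2], 1L)
        rf <- sample(spec$flank_length[1]:spec$flank_length[2], 1L)
        tibble(
          id = sprintf("c%02d_s%04d", ci, si),
          sequence = paste0(.random_aa(lf), paste(dom, collapse = ""),
                            .random_aa(rf)),
          start = lf + 1L, end = lf + dl,
          label = sprintf("class_%02d", ci)
        )
      })
    })
    rows
  })
}

#' Chunk-reshuffle null sequences
#'
#' Segments each sequence into contiguous chunks of `chunk_length`
#' residues (a final shorter chunk stays intact as its own unit) and
#' permutes the chunks uniformly at random within the sequence. The
#' amino-acid multiset is preserved exactly while domain-level
#' arrangement is destroyed, producing pseudo-random sequences that
#' retain local protein-like context.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param chunk_length Chunk size in residues (default 5).
#' @param seed Optional integer seed.
#' @return Character vector of reshuffled sequences.
#' @export
chunk_shuffle <- function(sequences, chunk_length = 5L, seed = NULL) {
  if (chunk_length < 1L) abort("`chunk_length` must be at least 1.")
  if (any(!nzchar(sequences)) || anyNA(sequences)) {
    abort("Sequences must be non-empty.", class = "spinr_invalid_record")
  }
  shuffle_one <- function(sq) {
    n <- nchar(sq)
    starts <- seq(1L, n, by = chunk_length)
    chunks <- substring(sq, starts, pmin(starts + chunk_length - 1L, n))
    paste(chunks[sample.int(length(chunks))], collapse = "")
  }
  run <- function() vapply(sequences, shuffle_one, character(1), USE.NAMES = FALSE)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fully reshuffled null sequences
#'
#' Applies a uniform random permutation to the residues of each
#' sequence, preserving the amino-acid multiset but destroying all
#' sequential structure.
#'
#' @inheritParams chunk_shuffle
#' @return Character vector of permuted sequences.
#' @export
full_shuffle <- function(sequences, seed = NULL) {
  if (any(!nzchar(sequences)) || anyNA(sequences)) {
    abort("Sequences must be non-empty.", class = "spinr_invalid_record")
  }
  shuffle_one <- function(sq) {
    paste(sample(strsplit(sq, "")[[1]]), collapse = "")
  }
  run <- function() vapply(sequences, shuffle_one, character(1), USE.NAMES = FALSE)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
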