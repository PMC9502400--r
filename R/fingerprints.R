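# Binary molecular fingerprints.
#
# Six families are provided, all returning fixed-length 0/1 vectors:
#
#   morgan       circular (ECFP-style) environments, radius 2, hashed and
#                folded to 2048 bits
#   topological  linear atom-bond paths of 1-7 bonds, atom-typed by element
#                and aromaticity, hashed to 2048 bits
#   layered      the same path enumeration hashed under three atom/bond
#                abstraction layers (bond orders only; elements + bonds;
#                elements + aromaticity + bonds), 2048 bits
#   pattern      generic substructure patterns: paths of 1-4 bonds with
#                atoms reduced to ring/aromatic classes, plus single-atom
#                element patterns, 2048 bits
#   maccs        the 166 public MACCS structural keys (via OpenBabel)
#   pharm2d      2- and 3-point pharmacophore feature combinations (H-bond
#                acceptor/donor, positive/negative ionizable, aromatic ring)
#                with binned topological distances, hashed to 2048 bits
#
# All families are pure functions of the molecular graph, so any SMILES
# spelling of the same molecule yields the same vector.

.FP_FAMILIES <- c("morgan", "topological", "layered", "pattern", "maccs", "pharm2d")

# ---- Morgan (circular) ----------------------------------------------------

.fp_morgan_bits <- function(g, radius, n_bits) {
  inv <- vapply(seq_len(g$n), function(i) {
    .hash_ints(c(1L, g$atomic_num[i], g$degree[i], g$h_count[i],
                 g$charge[i] + 4L, g$in_ring[i], g$aromatic[i]))
  }, 0)
  ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_inv <- numeric(g$n)
      for (i in seq_len(g$n)) {
        nb <- g$adj[[i]]
        if (length(nb) == 0) {
          new_inv[i] <- .hash_ints(c(r, inv[i]))
          next
        }
        pair <- cbind(g$badj[[i]], inv[nb])
        ord <- order(pair[, 1], pair[, 2])
        new_inv[i] <- .hash_ints(c(r, inv[i], t(pair[ord, , drop = FALSE])))
      }
      inv <- new_inv
      ids <- c(ids, inv)
    }
  }
  unique(ids %% n_bits) + 1
}

# ---- Path enumeration (topological / layered / pattern) -------------------

# All simple paths with 1..max_bonds bonds, each reported once (the reverse
# orientation is suppressed via endpoint ordering; single-orientation output
# is fine because hashes canonicalize over reversal anyway).
.enum_paths <- function(g, max_bonds) {
  paths <- vector("list", 256L)
  np <- 0L
  atoms <- integer(max_bonds + 1L)
  bonds <- integer(max_bonds)
  visit <- logical(g$n)

  dfs <- function(cur, depth) {
    nb <- g$adj[[cur]]
    bc <- g$badj[[cur]]
    for (j in seq_along(nb)) {
      nxt <- nb[j]
      if (visit[nxt]) next
      atoms[depth + 1L] <<- nxt
      bonds[depth] <<- bc[j]
      if (atoms[1L] < nxt) {
        np <<- np + 1L
        if (np > length(paths)) length(paths) <<- 2L * np
        paths[[np]] <<- list(a = atoms[seq_len(depth + 1L)],
                             b = bonds[seq_len(depth)])
      }
      if (depth < max_bonds) {
        visit[nxt] <<- TRUE
        dfs(nxt, depth + 1L)
        visit[nxt] <<- FALSE
      }
    }
  }
  for (s in seq_len(g$n)) {
    atoms[1L] <- s
    visit[s] <- TRUE
    dfs(s, 1L)
    visit[s] <- FALSE
  }
  if (np == 0L) list() else paths[seq_len(np)]
}

# Interleave atom codes and bond codes, canonicalized over reversal.
.path_seq <- function(acode, bcode) {
  k <- length(acode)
  fwd <- numeric(2L * k - 1L)
  fwd[seq(1L, 2L * k - 1L, by = 2L)] <- acode
  if (k > 1L) fwd[seq(2L, 2L * k - 2L, by = 2L)] <- bcode
  rev_acode <- rev(acode)
  bwd <- fwd
  bwd[seq(1L, 2L * k - 1L, by = 2L)] <- rev_acode
  if (k > 1L) bwd[seq(2L, 2L * k - 2L, by = 2L)] <- rev(bcode)
  cmp <- fwd - bwd
  nz <- which(cmp != 0)
  if (length(nz) && cmp[nz[1]] > 0) bwd else fwd
}

.fp_topological_bits <- function(g, n_bits, min_path = 1L, max_path = 7L) {
  acode_all <- g$atomic_num * 2L + g$aromatic
  paths <- .enum_paths(g, max_path)
  ids <- vapply(paths, function(p) {
    if (length(p$b) < min_path) return(NA_real_)
    .hash_ints(c(2L, .path_seq(acode_all[p$a], p$b)))
  }, 0)
  ids <- ids[!is.na(ids)]
  if (!length(ids)) return(integer(0))
  unique(ids %% n_bits) + 1
}

.fp_layered_bits <- function(g, n_bits, max_path = 7L) {
  el <- g$atomic_num
  ar <- g$atomic_num * 2L + g$aromatic
  paths <- .enum_paths(g, max_path)
  ids <- unlist(lapply(paths, function(p) {
    c(.hash_ints(c(31L, .path_seq(rep(0L, length(p$a)), p$b))),
      .hash_ints(c(32L, .path_seq(el[p$a], p$b))),
      .hash_ints(c(33L, .path_seq(ar[p$a], p$b))))
  }))
  if (is.null(ids)) return(integer(0))
  unique(ids %% n_bits) + 1
}

.fp_pattern_bits <- function(g, n_bits, max_path = 4L) {
  gcode <- 1L + 2L * g$in_ring + 4L * g$aromatic
  paths <- .enum_paths(g, max_path)
  ids <- vapply(paths, function(p) {
    .hash_ints(c(4L, .path_seq(gcode[p$a], p$b)))
  }, 0)
  ids <- c(ids, vapply(seq_len(g$n), function(i) {
    .hash_ints(c(40L, g$atomic_num[i], gcode[i]))
  }, 0))
  unique(ids %% n_bits) + 1
}

# ---- 2D pharmacophore -----------------------------------------------------

# Feature types: 1 H-bond acceptor, 2 H-bond donor, 3 positive ionizable,
# 4 negative ionizable, 5 aromatic ring. Each feature is a set of atoms (a
# single atom, or a whole aromatic ring); feature-feature distance is the
# minimum topological distance between member atoms, binned as
# 0-2 -> 1, 3-5 -> 2, 6-8 -> 3, >8 -> 4.
.pharm_features <- function(g) {
  feats <- list()
  add <- function(type, atoms) feats[[length(feats) + 1L]] <<- list(t = type, a = atoms)

  is_N <- g$element == "N"
  is_O <- g$element == "O"

  # carbonyl carbons (C with a double bond to O)
  carbonyl_C <- vapply(seq_len(g$n), function(i) {
    g$element[i] %in% c("C", "S") &&
      any(g$badj[[i]] == 2L & g$element[g$adj[[i]]] == "O")
  }, FALSE)

  for (i in seq_len(g$n)) {
    if (is_N[i] || is_O[i]) {
      # donor: N/O bearing at least one hydrogen
      if (g$h_count[i] >= 1L) add(2L, i)
      # acceptor: N/O except pyrrole-type aromatic NH
      if (!(is_N[i] && g$aromatic[i] && g$h_count[i] >= 1L)) add(1L, i)
    }
    # positive ionizable: basic amine nitrogen (non-aromatic N with no
    # adjacent carbonyl/sulfonyl group)
    if (is_N[i] && !g$aromatic[i] && !any(carbonyl_C[g$adj[[i]]])) add(3L, i)
    # negative ionizable: acidic group center (C/S carrying =O and -OH)
    if (carbonyl_C[i]) {
      oh <- g$badj[[i]] == 1L & g$element[g$adj[[i]]] == "O" &
        g$h_count[g$adj[[i]]] >= 1L
      if (any(oh)) add(4L, i)
    }
  }
  for (ring in g$arom_rings) add(5L, ring)
  feats
}

.pharm_bin <- function(d) {
  ifelse(d <= 2, 1L, ifelse(d <= 5, 2L, ifelse(d <= 8, 3L, 4L)))
}

.fp_pharm2d_bits <- function(g, n_bits) {
  feats <- .pharm_features(g)
  nf <- length(feats)
  if (nf < 2L) return(integer(0))
  dist <- .topo_distances(g)
  fdist <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in seq(i + 1L, nf)) {
      fdist[i, j] <- fdist[j, i] <-
        min(dist[feats[[i]]$a, feats[[j]]$a])
    }
  }
  types <- vapply(feats, `[[`, 0L, "t")
  ids <- numeric(0)
  # 2-point pharmacophores
  for (i in seq_len(nf - 1L)) {
    for (j in seq(i + 1L, nf)) {
      if (!is.finite(fdist[i, j])) next
      tt <- sort(c(types[i], types[j]))
      ids <- c(ids, .hash_ints(c(6L, tt, .pharm_bin(fdist[i, j]))))
    }
  }
  # 3-point pharmacophores: canonical code over the 6 vertex orderings
  if (nf >= 3L) {
    trip <- utils::combn(nf, 3L)
    perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                    nrow = 6, byrow = TRUE)
    for (c_i in seq_len(ncol(trip))) {
      v <- trip[, c_i]
      if (!all(is.finite(fdist[v, v]))) next
      best <- NULL
      for (p in seq_len(6)) {
        o <- v[perms[p, ]]
        code <- c(types[o[1]], types[o[2]], types[o[3]],
                  .pharm_bin(fdist[o[1], o[2]]),
                  .pharm_bin(fdist[o[1], o[3]]),
                  .pharm_bin(fdist[o[2], o[3]]))
        if (is.null(best)) {
          best <- code
        } else {
          cmp <- code - best
          nz <- which(cmp != 0)
          if (length(nz) && cmp[nz[1]] < 0) best <- code
        }
      }
      ids <- c(ids, .hash_ints(c(7L, best)))
    }
  }
  if (!length(ids)) return(integer(0))
  unique(ids %% n_bits) + 1
}

# ---- MACCS ----------------------------------------------------------------

.fp_maccs_matrix <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  if (!is.list(mols)) mols <- list(mols)
  if (length(mols) != length(smiles)) {
    .stopf("MACCS fingerprinting parsed %d of %d molecules",
           length(mols), length(smiles))
  }
  fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (!is.matrix(fp)) fp <- matrix(fp, nrow = 1)
  m <- fp[, seq_len(166), drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# ---- public API -----------------------------------------------------------

#' Compute a binary fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of standardized SMILES
#'   (see [standardize_structure()]).
#' @param family fingerprint family: one of `"morgan"`, `"topological"`,
#'   `"layered"`, `"pattern"`, `"maccs"`, `"pharm2d"`.
#' @param radius Morgan environment radius (default 2).
#' @param n_bits folded vector length for the hashed families (default 2048;
#'   MACCS is fixed at 166 keys).
#' @return integer 0/1 matrix, one row per molecule, with attributes
#'   `family` and `params`.
#' @export
fingerprint_matrix <- function(smiles, family = "morgan", radius = 2L,
                               n_bits = 2048L) {
  family <- match.arg(tolower(family), .FP_FAMILIES)
  if (!is.character(smiles) || length(smiles) == 0) {
    .stopf("'smiles' must be a non-empty character vector")
  }
  if (family == "maccs") {
    m <- .fp_maccs_matrix(smiles)
    params <- list(n_bits = 166L, keys = "public-166")
  } else {
    n_bits <- as.integer(n_bits)
    graphs <- .mol_graphs(smiles)
    bits <- switch(family,
      morgan      = lapply(graphs, .fp_morgan_bits, radius = as.integer(radius),
                           n_bits = n_bits),
      topological = lapply(graphs, .fp_topological_bits, n_bits = n_bits),
      layered     = lapply(graphs, .fp_layered_bits, n_bits = n_bits),
      pattern     = lapply(graphs, .fp_pattern_bits, n_bits = n_bits),
      pharm2d     = lapply(graphs, .fp_pharm2d_bits, n_bits = n_bits)
    )
    m <- matrix(0L, length(smiles), n_bits)
    for (i in seq_along(bits)) m[i, bits[[i]]] <- 1L
    params <- switch(family,
      morgan      = list(radius = as.integer(radius), n_bits = n_bits),
      topological = list(min_path = 1L, max_path = 7L, n_bits = n_bits),
      layered     = list(max_path = 7L, layers = 3L, n_bits = n_bits),
      pattern     = list(max_path = 4L, n_bits = n_bits),
      pharm2d     = list(features = c("acceptor", "donor", "pos_ionizable",
                                      "neg_ionizable", "aromatic"),
                         points = 2:3, distance_bins = c(2, 5, 8),
                         n_bits = n_bits)
    )
  }
  attr(m, "family") <- family
  attr(m, "params") <- params
  m
}

#' Compute the fingerprint of a single molecule
#'
#' @inheritParams fingerprint_matrix
#' @param smiles one standardized SMILES string.
#' @return integer 0/1 vector with attributes `family` and `params`.
#' @examples
#' fp <- compute_fingerprint("CCO", "morgan")
#' sum(fp)  # number of set bits
#' @export
compute_fingerprint <- function(smiles, family = "morgan", radius = 2L,
                                n_bits = 2048L) {
  stopifnot(length(smiles) == 1)
  m <- fingerprint_matrix(smiles, family, radius, n_bits)
  v <- m[1, ]
  attr(v, "family") <- attr(m, "family")
  attr(v, "params") <- attr(m, "params")
  v
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `T(a, b) = c / (|a| + |b| - c)` with `c` the number of shared on-bits.
#' Two all-zero vectors are defined as identical (`T = 1`); this degenerate
#' case is reported with a message.
#'
#' @param a,b binary vectors of equal length (and equal family, if tagged).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  if (length(a) != length(b)) .stopf("fingerprint lengths differ (%d vs %d)",
                                     length(a), length(b))
  fa <- attr(a, "family"); fb <- attr(b, "family")
  if (!is.null(fa) && !is.null(fb) && !identical(fa, fb)) {
    .stopf("fingerprint families differ (%s vs %s)", fa, fb)
  }
  ca <- sum(a != 0); cb <- sum(b != 0)
  cc <- sum(a != 0 & b != 0)
  if (ca + cb == 0) {
    message("tanimoto_similarity: both fingerprints empty; returning 1")
    return(1)
  }
  cc / (ca + cb - cc)
}

#' Write a fingerprint matrix with a sidecar parameter manifest
#'
#' Stores the 0/1 matrix as CSV and the family/parameter metadata as JSON
#' next to it.
#'
#' @param fp matrix from [fingerprint_matrix()].
#' @param path output CSV path; the manifest is written to `<path>.json`.
#' @return invisibly, `path`.
#' @export
write_fingerprints <- function(fp, path) {
  utils::write.table(fp, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(family = attr(fp, "family"), params = attr(fp, "params"),
         n_molecules = nrow(fp)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
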