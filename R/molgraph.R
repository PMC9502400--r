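# Lightweight molecular graphs.
#
# The hashed fingerprint families operate on a plain graph view of each
# molecule: per-atom element / charge / implicit-hydrogen / ring / aromatic
# flags and a bond list with orders. Structures are parsed by OpenBabel
# (ChemmineR::smiles2sdf) and ring perception / aromaticity comes from
# ChemmineR::rings() on the smallest set of rings; everything else is derived
# here. Inputs are expected to be standardized SMILES (see
# [standardize_structure()]), so charges are rare and stereochemistry is
# ignored.

# Old-style SDF atom-block charge codes -> formal charges.
.SDF_CHARGE <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)

.STANDARD_VALENCE <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = 3L, S = 2L,
  Cl = 1L, Br = 1L, I = 1L, Se = 2L
)

.ATOMIC_NUM <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Br = 35L, I = 53L, Se = 34L, Na = 11L, K = 19L,
  Ca = 20L, Mg = 12L, Zn = 30L, Fe = 26L
)

# Implicit hydrogens from standard valence, charge-adjusted for N/O/S/C.
.implicit_h <- function(element, bond_sum, charge) {
  val <- .STANDARD_VALENCE[[element]]
  if (is.null(val)) return(0L)
  if (charge != 0) {
    if (element == "N") val <- val + charge
    if (element == "O") val <- val + charge
    if (element == "C") val <- val - abs(charge)
    if (element == "S") val <- val + charge
  }
  # Hypervalent neutral S and P (sulfones, phosphates).
  if (element == "S" && bond_sum > val) val <- if (bond_sum <= 4L) 4L else 6L
  if (element == "P" && bond_sum > val) val <- 5L
  max(0L, as.integer(val) - as.integer(bond_sum))
}

# Parse one ChemmineR SDF object into a graph list.
.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(n)
  charge_code[is.na(charge_code) | charge_code < 0 | charge_code > 7] <- 0L
  charge <- .SDF_CHARGE[charge_code + 1L]

  # bond-free molecules yield a placeholder bond block without an order column
  if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3 || all(bb[, 1] == 0)) {
    a1 <- integer(0); a2 <- integer(0); order <- integer(0)
  } else {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    order <- as.integer(bb[, 3])
  }

  # Ring perception on the smallest set of rings; aromatic flags per ring.
  in_ring <- logical(n)
  aromatic <- logical(n)
  arom_bond <- logical(length(a1))
  arom_rings <- list()
  if (n > 2 && length(a1) >= 3) {
    rr <- tryCatch(
      ChemmineR::rings(sdf, upper = 10, type = "all", arom = TRUE, inner = TRUE),
      error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS)) {
      idx_of <- function(atoms) match(atoms, rownames(ab))
      for (k in seq_along(rr$RINGS)) {
        idx <- idx_of(rr$RINGS[[k]])
        in_ring[idx] <- TRUE
        if (isTRUE(rr$AROMATIC[[k]])) {
          aromatic[idx] <- TRUE
          arom_rings[[length(arom_rings) + 1L]] <- idx
          ring_pairs <- cbind(idx, c(idx[-1], idx[1]))
          for (r in seq_len(nrow(ring_pairs))) {
            hit <- (a1 == ring_pairs[r, 1] & a2 == ring_pairs[r, 2]) |
                   (a1 == ring_pairs[r, 2] & a2 == ring_pairs[r, 1])
            arom_bond[hit] <- TRUE
          }
        }
      }
    }
  }
  bond_code <- order
  bond_code[arom_bond] <- 4L

  bond_sum <- numeric(n)
  if (length(a1)) {
    for (b in seq_along(a1)) {
      bond_sum[a1[b]] <- bond_sum[a1[b]] + order[b]
      bond_sum[a2[b]] <- bond_sum[a2[b]] + order[b]
    }
  }
  h_count <- vapply(seq_len(n), function(i) {
    .implicit_h(element[i], bond_sum[i], charge[i])
  }, 0L)

  adj <- vector("list", n)
  badj <- vector("list", n)
  if (length(a1)) {
    for (b in seq_along(a1)) {
      adj[[a1[b]]] <- c(adj[[a1[b]]], a2[b])
      adj[[a2[b]]] <- c(adj[[a2[b]]], a1[b])
      badj[[a1[b]]] <- c(badj[[a1[b]]], bond_code[b])
      badj[[a2[b]]] <- c(badj[[a2[b]]], bond_code[b])
    }
  }

  list(n = n,
       element = element,
       atomic_num = unname(.ATOMIC_NUM[element]),
       charge = charge,
       h_count = h_count,
       degree = lengths(adj),
       in_ring = in_ring,
       aromatic = aromatic,
       bonds = cbind(a1 = a1, a2 = a2, code = bond_code),
       arom_rings = arom_rings,
       adj = adj,
       badj = badj)
}

# Single-atom graph built directly from the SMILES atom token (bond-free
# SDF records are not reliably round-tripped by the SDF reader).
.single_atom_graph <- function(smi) {
  tok <- .atom_tokens(smi)
  if (length(tok) != 1) .stopf("cannot parse structure '%s'", smi)
  el <- .token_element(tok)
  el <- paste0(toupper(substring(el, 1, 1)), substring(el, 2))
  list(n = 1L, element = el, atomic_num = unname(.ATOMIC_NUM[el]),
       charge = 0L, h_count = .implicit_h(el, 0, 0L), degree = 0L,
       in_ring = FALSE, aromatic = FALSE,
       bonds = cbind(a1 = integer(0), a2 = integer(0), code = integer(0)),
       arom_rings = list(), adj = list(NULL), badj = list(NULL))
}

# Parse a vector of standardized SMILES into graphs (one OpenBabel batch).
.mol_graphs <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  if (length(sdfs) != length(smiles)) {
    .stopf("structure parsing failed: %d of %d SMILES produced a molecule",
           length(sdfs), length(smiles))
  }
  lapply(seq_along(smiles), function(i) {
    g <- .graph_from_sdf(sdfs[[i]])
    if (anyNA(g$atomic_num)) g <- .single_atom_graph(smiles[i])
    g
  })
}

# All-pairs topological (bond-count) distances of one graph.
.topo_distances <- function(g) {
  if (g$n == 1) return(matrix(0, 1, 1))
  ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(ig) < g$n) {
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  }
  igraph::distances(ig)
}
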