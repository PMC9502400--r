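# Structure standardization.
#
# Raw bioactivity tables and vendor libraries carry salts, charged species and
# arbitrary SMILES spellings of the same molecule. Every structure entering
# the pipeline is funneled through one standardizer so that deduplication,
# fingerprinting and screening all see a single canonical, salt-free, neutral
# form per molecule. Chemistry (parsing, canonicalization, neutralization) is
# delegated to OpenBabel via ChemmineOB; the largest-organic-fragment salt
# rule is applied on top of it.

# One OpenBabel SMILES -> canonical SMILES conversion. Returns "" on parse
# failure (OpenBabel's convention).
.ob_canonical <- function(smiles, neutralize = FALSE) {
  out <- if (neutralize) {
    ChemmineOB::convertFormat("SMI", "CAN", smiles,
                              options = data.frame(names = "neutralize", args = ""))
  } else {
    ChemmineOB::convertFormat("SMI", "CAN", smiles)
  }
  sub("[ \t\n]+$", "", out)
}

# Atom tokens of a SMILES fragment: bracket atoms, two-letter organic-subset
# halogens, then single-letter organic-subset atoms (aromatic included).
.atom_tokens <- function(frag) {
  m <- gregexpr("\\[[^]]*\\]|Cl|Br|[BCNOPSFIbcnops]", frag)[[1]]
  if (m[1] == -1) return(character(0))
  substring(frag, m, m + attr(m, "match.length") - 1)
}

# Element symbol of one atom token ("[NH3+]" -> "N", "Cl" -> "Cl").
.token_element <- function(tok) {
  if (startsWith(tok, "[")) {
    sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", tok)
  } else {
    tok
  }
}

.fragment_heavy_atoms <- function(frag) {
  el <- vapply(.atom_tokens(frag), .token_element, "")
  el[!(el %in% c("H", "h"))]
}

#' Standardize a SMILES structure
#'
#' Canonicalizes a SMILES string, strips salts and counterions by keeping the
#' largest organic (carbon-containing) fragment, neutralizes charges where
#' chemically possible, and returns the canonical SMILES of the result. The
#' operation is idempotent and maps all spellings of the same molecule to one
#' canonical string, which is the deduplication key used throughout the
#' pipeline.
#'
#' @param smiles character vector of SMILES strings.
#' @param on_error `"stop"` (default) to raise an error on the first
#'   unusable structure, or `"na"` to return `NA` for failed entries with the
#'   failure reasons in the `"reason"` attribute.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' standardize_structure("CC(=O)[O-].[Na+]")  # -> "CC(=O)O"
#' standardize_structure(c("OCC", "CCO"))     # both -> "CCO"
#' @export
standardize_structure <- function(smiles, on_error = c("stop", "na")) {
  on_error <- match.arg(on_error)
  if (!is.character(smiles) || length(smiles) == 0) {
    .stopf("'smiles' must be a non-empty character vector")
  }
  out <- rep(NA_character_, length(smiles))
  reason <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    res <- .standardize_one(smiles[i])
    if (is.na(res$smiles)) {
      if (on_error == "stop") {
        .stopf("cannot standardize '%s': %s", smiles[i], res$reason)
      }
      reason[i] <- res$reason
    } else {
      out[i] <- res$smiles
    }
  }
  if (on_error == "na") attr(out, "reason") <- reason
  out
}

.standardize_one <- function(smi) {
  fail <- function(why) list(smiles = NA_character_, reason = why)
  if (is.na(smi) || !nzchar(trimws(smi))) return(fail("invalid structure"))
  smi <- trimws(smi)
  can <- .ob_canonical(smi)
  if (!nzchar(can)) return(fail("invalid structure"))

  # Salt stripping: keep the largest organic fragment (ties -> first).
  # Dots in a canonical SMILES only separate disconnected fragments.
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1) {
    heavy <- lapply(frags, .fragment_heavy_atoms)
    organic <- vapply(heavy, function(e) any(e %in% c("C", "c")), FALSE)
    if (!any(organic)) return(fail("no organic fragment"))
    sizes <- vapply(heavy, length, 0L)
    sizes[!organic] <- -1L
    can <- frags[which.max(sizes)]
  }

  out <- .ob_canonical(can, neutralize = TRUE)
  if (!nzchar(out)) return(fail("invalid structure"))
  list(smiles = out, reason = NA_character_)
}
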