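# ---------------------------------------------------------------------------
# Residue correspondences between two structures: identical numbering,
# global sequence alignment, or an explicit user-supplied table.
# ---------------------------------------------------------------------------

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.residue_table <- function(s, chain, model_index = 1L) {
  a <- s$atoms[s$atoms$model_index == model_index &
                 s$atoms$chain_id == chain, , drop = FALSE]
  if (nrow(a) == 0) return(a[0, c("chain_id", "res_seq", "i_code", "res_name")])
  key <- .residue_key(a)
  a[!duplicated(key), c("chain_id", "res_seq", "i_code", "res_name")]
}

#' Global Needleman-Wunsch alignment of two sequences
#'
#' Scoring: match +1, mismatch -1, gap -2 (linear). Ties are broken
#' deterministically toward the diagonal, then toward a gap in the second
#' sequence (the leading-gap / upper-left path), so the alignment is unique.
#'
#' @param a,b character vectors of single letters.
#' @return data frame with columns `i`, `j`: 1-based indices of aligned
#'   (match/mismatch) columns only.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- gap * (0:m)
  S[, 1] <- gap * (0:n)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j],       # diagonal
                             S[i, j + 1] + gap,      # gap in b (up)
                             S[i + 1, j] + gap)      # gap in a (left)
    }
  }
  # traceback, tie order: diagonal, up (gap in b), left (gap in a)
  i <- n; j <- m
  pi <- integer(0); pj <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      pi <- c(i, pi); pj <- c(j, pj); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  data.frame(i = pi, j = pj)
}

#' Build a residue correspondence between two structures
#'
#' @param a,b structures.
#' @param mode `"by_resid"` pairs residues sharing `(res_seq, i_code)`;
#'   `"by_alignment"` pairs residues via global sequence alignment of
#'   one-letter codes (match +1, mismatch -1, gap -2, deterministic
#'   leading-gap tie-break), keeping aligned match/mismatch columns only.
#' @param chain_map optional named character vector mapping chains of `a` to
#'   chains of `b` (names = chains in `a`); defaults to identical chain ids
#'   present in both.
#' @return object of class `gatescope_correspondence`: a data frame of pairs
#'   `(chain_a, resseq_a, icode_a, chain_b, resseq_b, icode_b)` with a `mode`
#'   attribute. One-to-one by construction.
#' @export
build_correspondence <- function(a, b, mode = c("by_resid", "by_alignment"),
                                 chain_map = NULL) {
  mode <- match.arg(mode)
  if (is.null(chain_map)) {
    shared <- intersect(unique(a$atoms$chain_id), unique(b$atoms$chain_id))
    if (length(shared) == 0) stop("no shared chains between structures")
    chain_map <- setNames(shared, shared)
  }
  pairs <- list()
  for (ca in names(chain_map)) {
    cb <- chain_map[[ca]]
    ra <- .residue_table(a, ca)
    rb <- .residue_table(b, cb)
    if (nrow(ra) == 0 || nrow(rb) == 0) next
    if (mode == "by_resid") {
      ka <- paste(ra$res_seq, ra$i_code, sep = "|")
      kb <- paste(rb$res_seq, rb$i_code, sep = "|")
      common <- intersect(ka, kb)
      ia <- match(common, ka); ib <- match(common, kb)
    } else {
      sa <- unname(.aa3to1[ra$res_name]); sa[is.na(sa)] <- "X"
      sb <- unname(.aa3to1[rb$res_name]); sb[is.na(sb)] <- "X"
      al <- align_global(sa, sb)
      ia <- al$i; ib <- al$j
    }
    if (length(ia) == 0) next
    pairs[[ca]] <- data.frame(
      chain_a = ra$chain_id[ia], resseq_a = ra$res_seq[ia],
      icode_a = ra$i_code[ia],
      chain_b = rb$chain_id[ib], resseq_b = rb$res_seq[ib],
      icode_b = rb$i_code[ib], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(pairs))
  if (is.null(out) || nrow(out) == 0)
    stop("empty correspondence: no pairable residues")
  rownames(out) <- NULL
  structure(out, mode = mode, class = c("gatescope_correspondence", "data.frame"))
}

#' Build an explicit correspondence from a pair table
#'
#' Used for cross-species gate-loop residue pairings that are supplied as a
#' fixture rather than recomputed by alignment.
#'
#' @param pairs data frame with columns `chain_a`, `resseq_a`, `icode_a`,
#'   `chain_b`, `resseq_b`, `icode_b` (icode columns optional, default "").
#' @return a `gatescope_correspondence`.
#' @export
explicit_correspondence <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$icode_a)) pairs$icode_a <- ""
  if (is.null(pairs$icode_b)) pairs$icode_b <- ""
  cols <- c("chain_a", "resseq_a", "icode_a", "chain_b", "resseq_b", "icode_b")
  stopifnot(all(cols %in% names(pairs)))
  pairs <- pairs[, cols]
  ka <- paste(pairs$chain_a, pairs$resseq_a, pairs$icode_a)
  kb <- paste(pairs$chain_b, pairs$resseq_b, pairs$icode_b)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("correspondence must be one-to-one")
  structure(pairs, mode = "explicit",
            class = c("gatescope_correspondence", "data.frame"))
}

# Paired coordinates of named atoms for a correspondence. Pairs every atom
# of `a` (restricted to atom_names) with the same-named atom of the
# corresponding residue of `b`; atoms without a partner are dropped.
# Returns list(xa, xb): k x 3 matrices, plus the residue-pair index of each
# row in `which_pair`.
.paired_coords <- function(a, b, corr, atom_names = "CA",
                           model_a = 1L, model_b = 1L) {
  atab <- a$atoms[a$atoms$model_index == model_a &
                    a$atoms$name %in% atom_names, , drop = FALSE]
  btab <- b$atoms[b$atoms$model_index == model_b &
                    b$atoms$name %in% atom_names, , drop = FALSE]
  pa <- paste(corr$chain_a, corr$resseq_a, corr$icode_a)
  pb <- paste(corr$chain_b, corr$resseq_b, corr$icode_b)
  res_a <- paste(atab$chain_id, atab$res_seq, atab$i_code)
  # residue-pair index of each atom of a (NA if residue not in corr)
  pair_idx <- match(res_a, pa)
  key_b <- paste(btab$chain_id, btab$res_seq, btab$i_code, btab$name)
  want_b <- ifelse(is.na(pair_idx), NA, paste(pb[pair_idx], atab$name))
  ib <- match(want_b, key_b)
  ok <- !is.na(pair_idx) & !is.na(ib)
  list(xa = as.matrix(atab[ok, c("x", "y", "z")]),
       xb = as.matrix(btab[ib[ok], c("x", "y", "z")]),
       which_pair = pair_idx[ok])
}
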