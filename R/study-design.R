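# The study catalog: eight sequence classes around a variable central pair,
# symmetry reduction of the palindromic class, and counterion arithmetic.

# Central placeholder is marked X/Y; chain B written 5'->3'.
.SEQUENCE_CLASSES <- list(
  I  = list(chain_a = "GGTTAAXTTAACC",   palindromic = TRUE,
            comment = "palindromic 13-mer, central AAXTT"),
  II = list(chain_a = "GAACCGCXCGCTAGG", palindromic = FALSE,
            comment = "15-mer from a MutS/DNA crystal, central GCXCG"),
  III = list(chain_a = "GAACCAAXTTCTAGG", palindromic = FALSE,
             comment = "15-mer, central AAXTT as in class I"),
  C1 = list(chain_a = "GAACCAAXAACTAGG", palindromic = FALSE,
            comment = "coldspot context AAXAA (Fisher P = 1.3e-6)"),
  C2 = list(chain_a = "GAACCCAXTGCTAGG", palindromic = FALSE,
            comment = "coldspot context CAXTG (Fisher P = 9.2e-5)"),
  H1 = list(chain_a = "GAACCAGXTACTAGG", palindromic = FALSE,
            comment = "hotspot context AGXTA (Fisher P = 1.3e-11)"),
  H2 = list(chain_a = "GAACCTCXCACTAGG", palindromic = FALSE,
            comment = "hotspot context TCXCA (Fisher P = 2.7e-8)"),
  H3 = list(chain_a = "GAACCTGXAACTAGG", palindromic = FALSE,
            comment = "hotspot context TGXAA (Fisher P = 6.6e-4)")
)

# Non-palindromic classes were each simulated with the two canonical pairs
# and the G/T mismatch only.
.NONPALINDROMIC_SYSTEMS <- list(
  list(X = "A", Y = "T", orient = c("anti", "anti")),
  list(X = "G", Y = "C", orient = c("anti", "anti")),
  list(X = "G", Y = "T", orient = c("anti", "anti"))
)

# Representative preference for the palindromic strand-swap equivalence
# (X,orient1)/(Y,orient2) == (Y,orient2)/(X,orient1): keep the form whose
# chain-A base comes first in purine-then-pyrimidine order A, G, C, T; for
# X == Y, anti on chain A is preferred.
.BASE_PRIORITY <- c(A = 1, G = 2, C = 3, T = 4)

#' List the sequence classes of the study catalog
#' @return data.frame: class, chain_a (with X placeholder), chain_b,
#'   length_nt, palindromic, comment.
#' @export
sequence_classes <- function() {
  comp_seq <- function(s) {
    chartr("ACGTX", "TGCAY", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  do.call(rbind, lapply(names(.SEQUENCE_CLASSES), function(nm) {
    cl <- .SEQUENCE_CLASSES[[nm]]
    data.frame(class = nm, chain_a = cl$chain_a,
               chain_b = comp_seq(cl$chain_a),
               length_nt = nchar(cl$chain_a),
               palindromic = cl$palindromic, comment = cl$comment)
  }))
}

.annotate <- function(X, Y, orient) {
  canonical <- (X == "A" && Y == "T" && all(orient == "anti")) ||
    (X == "G" && Y == "C" && all(orient == "anti")) ||
    (X == "T" && Y == "A" && all(orient == "anti")) ||
    (X == "C" && Y == "G" && all(orient == "anti"))
  sep <- if (canonical) ":" else "/"
  paste0(substr(orient[1], 1, 1), X, sep, substr(orient[2], 1, 1), Y)
}

#' Enumerate the unique simulation systems of a sequence class
#'
#' For the palindromic class I all 16 X/Y combinations in the anti/anti,
#' anti/syn and syn/anti orientation families (48 candidates) are reduced
#' under the strand-swap equivalence (X,Y,o1/o2) == (Y,X,o2/o1) to 26 unique
#' systems.  Non-palindromic classes return their fixed three-system list.
#'
#' @param class_name One of "I", "II", "III", "C1", "C2", "H1", "H2", "H3".
#' @param candidates Return the full candidate list before symmetry
#'   reduction (palindromic classes only).
#' @return data.frame: class, X, Y, orient_x, orient_y, canonical,
#'   annotation.
#' @export
enumerate_systems <- function(class_name, candidates = FALSE) {
  cl <- .SEQUENCE_CLASSES[[class_name]]
  if (is.null(cl)) stop("unknown sequence class: ", class_name)
  bases <- c("A", "C", "G", "T")
  mk <- function(X, Y, o1, o2) {
    data.frame(class = class_name, X = X, Y = Y, orient_x = o1, orient_y = o2,
               canonical = grepl(":", .annotate(X, Y, c(o1, o2)), fixed = TRUE),
               annotation = .annotate(X, Y, c(o1, o2)))
  }
  if (!cl$palindromic) {
    return(do.call(rbind, lapply(.NONPALINDROMIC_SYSTEMS, function(s) {
      mk(s$X, s$Y, s$orient[1], s$orient[2])
    })))
  }
  fams <- list(c("anti", "anti"), c("anti", "syn"), c("syn", "anti"))
  all_sys <- do.call(rbind, lapply(fams, function(o) {
    do.call(rbind, lapply(bases, function(X) {
      do.call(rbind, lapply(bases, function(Y) mk(X, Y, o[1], o[2])))
    }))
  }))
  if (candidates) return(all_sys)
  key <- character(nrow(all_sys))
  keep_first <- logical(nrow(all_sys))
  for (i in seq_len(nrow(all_sys))) {
    a <- paste0(all_sys$orient_x[i], all_sys$X[i])
    b <- paste0(all_sys$orient_y[i], all_sys$Y[i])
    key[i] <- paste(sort(c(a, b)), collapse = "|")
    px <- .BASE_PRIORITY[[all_sys$X[i]]]; py <- .BASE_PRIORITY[[all_sys$Y[i]]]
    keep_first[i] <- px < py ||
      (px == py && all_sys$orient_x[i] == "anti")
  }
  # within each equivalence class keep the preferred spelling
  ord <- order(!keep_first)
  out <- all_sys[ord, ][!duplicated(key[ord]), ]
  rownames(out) <- NULL
  out
}

#' Total number of systems in the catalog
#'
#' Class I unique systems plus three systems for each of the seven
#' non-palindromic classes.
#'
#' @param classes Optional subset of class names.
#' @return Integer count (47 for the full catalog).
#' @export
catalog_total <- function(classes = names(.SEQUENCE_CLASSES)) {
  if (length(classes) == 0) return(0L)
  sum(vapply(classes, function(cn) nrow(enumerate_systems(cn)), integer(1)))
}

#' Neutralizing counterion count for a blunt duplex
#'
#' A duplex of n nucleotides per strand without terminal 5'-phosphates
#' carries 2(n - 1) backbone phosphates, hence 2(n - 1) monovalent cations
#' for electroneutrality; with terminal 5'-phosphates, 2n.
#'
#' @param duplex_length_nt Nucleotides per strand (>= 2).
#' @param five_prime_phosphate Terminal 5'-phosphates present?
#' @return Integer cation count (24 for 13-mers, 28 for 15-mers).
#' @export
counterion_count <- function(duplex_length_nt, five_prime_phosphate = FALSE) {
  n <- as.integer(duplex_length_nt)
  if (n < 2) stop("duplex length must be >= 2 nt")
  if (five_prime_phosphate) 2L * n else 2L * (n - 1L)
}
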