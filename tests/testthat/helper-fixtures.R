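# Shared helpers: small builders used across test files.

random_cloud <- function(n, box = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- clashaudit:::empty_atoms(n)
  a$serial <- seq_len(n)
  a$name <- "C"
  a$altloc <- ""
  a$resname <- "LIG"
  a$chain <- "X"
  a$resseq <- seq_len(n)
  a$icode <- ""
  a$x <- runif(n, 0, box); a$y <- runif(n, 0, box); a$z <- runif(n, 0, box)
  a$occ <- 1; a$b <- 0
  a$element <- "C"
  a$het <- TRUE
  structure_model(a)
}

brute_force_pairs <- function(model, cutoff) {
  xyz <- coords(model)
  d <- as.matrix(dist(xyz))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
}

pair_key <- function(p) paste(p[, 1], p[, 2], sep = "-")

# an all-atom helical test peptide used by several files
helical_allatom <- function(sequence = "GSNTAYKE") {
  add_hydrogens(build_ideal_peptide(sequence, phi = -57, psi = -47))
}
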