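# Small fixtures built in code, shared across test files.

# tiny labelled count matrix: 4 observations x 3 genes
tiny_counts <- function() {
  m <- Matrix::Matrix(matrix(c(1, 0, 2,
                               0, 3, 1,
                               4, 0, 0,
                               0, 0, 5), 4, 3, byrow = TRUE), sparse = TRUE)
  dimnames(m) <- list(paste0("obs", 1:4), paste0("g", 1:3))
  m
}

# two perfectly separated types on disjoint gene blocks
separated_types <- function(n_per_type = 20, n_genes = 40, depth = 50, seed = 11) {
  set.seed(seed)
  half <- n_genes / 2
  m <- matrix(0, 2 * n_per_type, n_genes)
  m[seq_len(n_per_type), seq_len(half)] <-
    rpois(n_per_type * half, depth / half)
  m[n_per_type + seq_len(n_per_type), half + seq_len(half)] <-
    rpois(n_per_type * half, depth / half)
  dimnames(m) <- list(sprintf("cell%03d", seq_len(2 * n_per_type)),
                      sprintf("g%03d", seq_len(n_genes)))
  anno <- setNames(rep(c("A", "B"), each = n_per_type), rownames(m))
  list(counts = Matrix::Matrix(m, sparse = TRUE), anno = anno)
}

# two spatially segregated molecule blobs emitting disjoint gene sets
planted_molecules <- function(n_per_blob = 400, gap = 60, spread = 8, seed = 5) {
  set.seed(seed)
  genes_a <- paste0("ga", 1:5)
  genes_b <- paste0("gb", 1:5)
  mol <- data.frame(
    x = c(rnorm(n_per_blob, 0, spread), rnorm(n_per_blob, gap, spread)),
    y = c(rnorm(n_per_blob, 0, spread), rnorm(n_per_blob, 0, spread)),
    gene = c(sample(genes_a, n_per_blob, TRUE), sample(genes_b, n_per_blob, TRUE)),
    truth = rep(c("A", "B"), each = n_per_blob)
  )
  profiles <- matrix(0, 10, 2, dimnames = list(c(genes_a, genes_b), c("A", "B")))
  profiles[genes_a, "A"] <- 1 / 5
  profiles[genes_b, "B"] <- 1 / 5
  list(mol = mol, profiles = profiles)
}
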