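# Fixtures built in code: a small hand-crafted cell table plus helpers.

# 10 cells: 4 tumor (Pax8+), 3 CD8 (2 PD-1+, 1 of those TOX+), 1 Treg,
# 2 unlabeled; PD-L1 on two tumor cells.
make_toy_cells <- function(specimen = "TOY1") {
  cell_table(
    specimen,
    cell_id = sprintf("t%02d", 1:10),
    x = c(10, 20, 30, 40, 12, 22, 32, 50, 60, 70),
    y = c(10, 10, 10, 10, 14, 14, 14, 40, 40, 40),
    compartment = c(rep("tumor", 7), rep("stroma", 3)),
    markers = data.frame(
      CD8   = c(FALSE, FALSE, FALSE, FALSE, TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE),
      PD1   = c(FALSE, FALSE, FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE),
      TOX   = c(FALSE, FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE),
      FOXP3 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE),
      PDL1  = c(TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      PAX8  = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)))
}

# random cell table with independent marker calls (no marker logic)
make_random_cells <- function(n, seed, specimen = "RND1", extent = 500) {
  set.seed(seed)
  cell_table(
    specimen,
    cell_id = sprintf("r%04d", seq_len(n)),
    x = round(runif(n, 0, extent), 2),
    y = round(runif(n, 0, extent), 2),
    compartment = sample(c("tumor", "stroma"), n, replace = TRUE),
    markers = data.frame(
      CD8 = runif(n) < 0.3, PD1 = runif(n) < 0.3, TOX = runif(n) < 0.3,
      FOXP3 = runif(n) < 0.2, PDL1 = runif(n) < 0.4, PAX8 = runif(n) < 0.5))
}

# scaled-down simulation parameters for fast unit tests
small_sim_params <- function(...) {
  args <- list(region = c(width = 500, height = 500), n_nests = 3,
               nest_radius = 100, lambda_tumor = 1500, lambda_cd8 = 250,
               lambda_treg = 80, lambda_other = 500)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_params, args)
}
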