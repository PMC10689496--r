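# Shared fixtures: tiny trees and cognate matrices built in code.

two_tip_tree <- function(t1 = 1000, t2 = 1000) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", t1, t2))
}

three_tip_tree <- function() {
  ape::read.tree(text = "((A:500,B:500):500,C:1000);")
}

tiny_matrix <- function(cells, concept = "c1") {
  langs <- rownames(cells)
  cognate_matrix(
    cells,
    data.frame(
      concept_id = rep_len(concept, ncol(cells)),
      cognate_id = paste0(rep_len(concept, ncol(cells)), ".", seq_len(ncol(cells)))
    ),
    stats::setNames(rep(0, length(langs)), langs)
  )
}

random_cognate_matrix <- function(seed, n_concepts = 6, n_langs = 4) {
  set.seed(seed)
  langs <- paste0("L", seq_len(n_langs))
  cols <- sample(1:3, n_concepts, replace = TRUE)
  concept_id <- rep(sprintf("c%02d", seq_len(n_concepts)), cols)
  n_col <- length(concept_id)
  cells <- matrix(sample(c(0L, 1L), n_langs * n_col, replace = TRUE),
                  n_langs, n_col, dimnames = list(langs, NULL))
  # every column observable
  for (j in seq_len(n_col)) if (!any(cells[, j] == 1L)) cells[1, j] <- 1L
  cognate_matrix(
    cells,
    data.frame(concept_id = concept_id,
               cognate_id = paste0(concept_id, ".",
                                   stats::ave(seq_len(n_col), concept_id,
                                              FUN = seq_along))),
    stats::setNames(rep(0, n_langs), langs)
  )
}

# small simulated world shared by niche/biome tests
small_world <- function(seed = 3, slices = 3) {
  cfg <- sim_config(seed, climate = list(n_time_slices = slices))
  list(cfg = cfg, grids = simulate_climate_series(cfg))
}
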