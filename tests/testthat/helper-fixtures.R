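# Shared fixtures: tiny panels and configs built in code.

tiny_panel <- function() {
  ResponsePanel(data.frame(
    cell_id = c("C1", "C2", "C1", "C2", "C3"),
    drug_id = c("D1", "D1", "D2", "D2", "D2"),
    response = c(0.5, -1.2, 2.0, 0.1, 1.1)), metric = "IC50")
}

# a small but trainable panel: 4 mechanisms x 3 drugs, 40 cells
small_sim <- function(seed = 5, ...) {
  generatePanel(simConfig(n_mechanisms = 4, drugs_per_mechanism = 3,
                          n_cells = 40, n_cell_features = 60,
                          fingerprint_width = 64, seed = seed, ...))
}

# fast model config for tiny fixtures
tiny_model <- function(...) {
  modelConfigSynthetic(cell_arm_widths = c(32L, 16L),
                       drug_arm_widths = c(16L, 8L), head_widths = 8L,
                       max_epochs = 30L, patience = 4L, ...)
}

write_tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

expect_valid <- function(object) expect_true(methods::validObject(object))
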