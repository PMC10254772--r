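# Shared fixtures. The trained toy models are expensive (~minutes), so they
# are built lazily, once per test run, and shared by the sampler, training,
# and acceptance tests.

the_fixtures <- new.env(parent = emptyenv())

# a small random-weight model over a fixed vocabulary, for structural tests
make_random_tiny_model <- function(n_conditions = 2L, seed = 7L,
                                   vocab_smiles = c("CCO", "c1ccccc1F",
                                                    "CC(Cl)C", "N#Cc1ccncc1")) {
  vocab <- build_vocabulary(vocab_smiles)
  cfg <- tiny_config(vocab_size = length(vocab), n_conditions = n_conditions)
  structure(list(params = init_params(cfg, seed = seed), config = cfg,
                 vocab = vocab,
                 condition_labels = paste0("T", seq_len(n_conditions) - 1L),
                 log = data.frame()),
            class = "condsmiles_model")
}

# the stated desk-scale world: 5,000 toy molecules, tiny preset,
# pre-training then conditional fine-tuning, fixed seeds
toy_corpus <- function() {
  if (is.null(the_fixtures$corpus)) {
    the_fixtures$corpus <- sample_toy_molecules(default_toy_spec(),
                                                n = 5000, seed = 101)
  }
  the_fixtures$corpus
}

desk_pretrain_config <- function() {
  training_config(n_epochs = 10L, seed = 1L, learning_rate = 1e-3)
}

desk_finetune_config <- function() {
  training_config(n_epochs = 5L, seed = 2L, learning_rate = 1e-3)
}

trained_base_model <- function() {
  if (is.null(the_fixtures$base)) {
    recs <- toy_corpus()
    cfg <- tiny_config(vocab_size = 4L, n_conditions = 2L)
    the_fixtures$base <- pretrain(recs, cfg, desk_pretrain_config())
  }
  the_fixtures$base
}

trained_conditional_model <- function() {
  if (is.null(the_fixtures$ft)) {
    the_fixtures$ft <- finetune(trained_base_model(), toy_corpus(),
                                desk_finetune_config())
  }
  the_fixtures$ft
}
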