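## Shared builders for small test objects.  Values are chosen to be easy to
## verify by hand; they do not correspond to any particular trial.

test_breed <- function(...) {
  args <- list(
    name = "test crossbred", species_class = "crossbred", sex = "female",
    birth_weight = 30, max_attainable_weight = 500, min_mature_weight = 280,
    peak_milk_yield = 20, peak_month = 2, lactation_length = 10,
    milk_fat = 46.3, milk_protein = 29
  )
  do.call(breed_parameters, utils::modifyList(args, list(...)))
}

test_state <- function(...) {
  args <- list(age = 5.2, body_weight = 415, lactation_month = 1)
  do.call(animal_state, utils::modifyList(args, list(...)))
}

test_ration <- function(...) {
  args <- list(dm = 890, me = 9.4, ndf = 0.55, cp = 93.1)
  do.call(ration, utils::modifyList(args, list(...)))
}

test_scenario <- function(..., n_steps = 5) {
  scenario(breed = test_breed(), initial_state = test_state(),
           ration = test_ration(), n_steps = n_steps, ...)
}
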