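# Shared fixtures built in code.

dill <- hydropathy_classification("dill")
dill_basis <- build_basis(dill)

# A noiseless matrix with known two-body structure.
noiseless_matrix <- function(eta_hh = 2, eta_hp = 1, eta_hb = 1,
                             eta0 = 0.5, q = NULL, basis = dill_basis,
                             name = "noiseless") {
  tr <- ground_truth(eta_hh = eta_hh, eta_hp = eta_hp, eta_hb = eta_hb,
                     eta0 = eta0, q = q,
                     classification = basis$classification, noise_sd = 0)
  generate_matrix(tr, seed = 1, name = name)$matrix
}

# A small symmetric contact matrix over a residue subset.
toy_matrix <- function(values, labels) {
  contact_matrix(values, labels, name = "toy")
}

# Unique pair count by closed-form combinatorics: C(k, 2) + k.
pairs_within <- function(k) k * (k - 1) / 2 + k
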