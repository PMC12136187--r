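# Shared fixtures: a small panel of drug-like SMILES and builders for the
# synthetic datasets used across tests.

drug_smiles <- c(
  aspirin      = "CC(=O)Oc1ccccc1C(=O)O",
  paracetamol  = "CC(=O)Nc1ccc(O)cc1",
  ibuprofen    = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  caffeine     = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  nicotine     = "CN1CCC[C@H]1c1cccnc1",
  naproxen     = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  atenolol     = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
  warfarin     = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
  diazepam     = "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
  procaine     = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
  lidocaine    = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
  metformin    = "CN(C)C(=N)NC(=N)N",
  salbutamol   = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
  theophylline = "Cn1c2nc[nH]c2c(=O)n(C)c1=O",
  benzocaine   = "CCOC(=O)c1ccc(N)cc1",
  phenacetin   = "CCOc1ccc(NC(C)=O)cc1",
  tolbutamide  = "CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1",
  isoniazid    = "NNC(=O)c1ccncc1",
  sulfanilamide = "Nc1ccc(cc1)S(N)(=O)=O",
  propranolol  = "CC(C)NCC(O)COc1cccc2ccccc12"
)

# two-class fingerprint set whose classes carry disjoint signature blocks
two_signature_fixture <- function(n_per_class = 800L, seed = 11L,
                                  length = 168L) {
  fa <- make_synthetic_fpset(n_active = n_per_class, n_inactive = 0L,
                             length = length, signature_bits = 1:20,
                             p_on_active = 0.9, background_p = 0.3,
                             seed = seed)
  fi <- make_synthetic_fpset(n_active = n_per_class, n_inactive = 0L,
                             length = length, signature_bits = 21:40,
                             p_on_active = 0.9, background_p = 0.3,
                             seed = seed + 1L)
  bits <- rbind(fa$fps$bits, fi$fps$bits)
  structure(
    list(fps = fp_set(bits, "MACCS"),
         labels = factor(rep(c("active", "inactive"), each = n_per_class),
                         levels = c("active", "inactive")),
         active = fa$fps, inactive = fi$fps),
    class = "fp_labeled_set"
  )
}

# brute-force per-bit Tanimoto, the oracle every fast path is checked against
naive_tanimoto <- function(a, b) {
  inter <- 0; union <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) union <- union + 1
  }
  if (union == 0) 0 else inter / union
}

# random binary fingerprint matrix
random_fp_matrix <- function(n, len = 64L, p = 0.3, seed = 1L) {
  set.seed(seed)
  matrix(rbinom(n * len, 1L, p), n, len)
}

# small training configuration used across training tests
tiny_config <- function(seed = 1L) {
  fp_training_config(d_epochs = 3L, gan_epochs = 3L, seed = seed,
                     d_learning_rate = 1e-4)
}
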