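# interformer

Per-residue prediction of protein binding interfaces from structure alone,
with a rotation-equivariant geometric transformer implemented entirely in
R.

## The problem

Knowing *where* a protein binds its partners — other proteins, nucleic
acids, ions, small molecules, lipids — is as valuable as knowing its fold,
and far less often annotated. `interformer` treats a structure as a point
cloud of atoms labelled only by element and predicts, for every residue, a
confidence in [0, 1] for each of five interface categories. There is no
surface computation, no physico-chemical parametrization and no sequence
profile.

## The model

Each atom carries a scalar state `q ∈ R^S` (rotation-invariant) and a
vector state `p ∈ R^{3×S}` (rotates with the structure, initialised to 0).
A geometric transformer block encodes every edge of the atom's
`nn`-nearest-neighbour graph from invariants only —

    q_i, q_j, d_ij, 1/d_ij, ⟨p_i, r̂_ij⟩, ⟨p_j, r̂_ij⟩, ⟨p_i, p_j⟩, ‖p_j‖

— runs multi-head attention over the `nn` slots (missing neighbours become
zero-state *sink* edges) and applies residual updates

    q_i ← q_i + MLP( Σ_j a_ij v_ij )
    p_i ← p_i + Σ_h Σ_j a_ij^h ( g_ij^h ⊗ r̂_ij + h_ij^h ⊙ p_j )

with invariant gates `g, h`, so scalar outputs are exactly invariant and
vector outputs exactly equivariant under rigid motions. The default
architecture stacks 4 sets of 8 blocks with neighbourhoods growing through
`nn = 8, 16, 32, 64`, pools atoms to residues by attention, collapses
vector states to channel norms, and decodes with a sigmoid MLP head.
Interface ground truth for training is geometric: a residue is an
interface residue when any heavy atom lies within 5 Å of a different
subunit, with categories from a 79-component molecule catalogue.

Because no deep-learning framework is available for R, the package ships
its own minimal reverse-mode autodiff tape and Adam optimizer, verified
against finite differences in the test suite.

## A worked example

Generate a synthetic two-chain complex with a planted contact, train a
small model on a seeded corpus, and score a held-out structure:

```r
library(interformer)

# a reproducible corpus of planted-interface complexes
cfg    <- synth_config(n_structures = 12, seed = 42)
corpus <- generate_corpus(cfg)
table(corpus$manifest$split)
#> test train valid
#>     2     8     2

# train a small model on the training split
mcfg <- model_config(S = 16, nn_schedule = list(c(2, 4), c(2, 8)),
                     channels = "protein")
tr   <- which(corpus$manifest$split == "train")
fit  <- train_model(build_model(mcfg, seed = 1),
                    corpus$structures[tr], corpus$labels[tr],
                    train_config(epochs = 4, seed = 1))

# score a held-out structure and compare with its ground truth
i    <- which(corpus$manifest$split == "test")[1]
pred <- predict(fit$params, corpus$structures[[i]])
head(pred, 3)
#>   chain_tag author_number residue_name    protein
#> 1       A:1             1          THR 0.05524...
#> 2       A:1             2          ILE 0.06241...
#> 3       A:1             3          SER 0.06457...

truth <- corpus$labels[[i]]$labels[, "protein"]
roc_auc(pred$protein, truth)
#> [1] 0.9654255
recovery_rate(pred$protein, truth)$rate
#> [1] 0.4
```

Eight training structures are enough for this toy model to rank the
held-out interface residues well (ROC AUC 0.97 here) even though its
absolute confidences stay low and only 40 % of the top-ranked decile are
true contacts; the full experiment in `scripts/acceptance.R` trains on 400
structures and exceeds AUC 0.99.  The first column block identifies the
residue (subunit tag, author numbering, name) and each remaining column is
a per-channel confidence — larger means more likely an interface.

Real PDB files go through the same pipeline:

```r
st   <- parse_structure("structure.pdb")   # cleaned: models merged, waters/H out
pred <- predict(fit$params, st)
write_prediction_pdb(st, pred, "protein", "scored.pdb")  # confidence in B-factor
write_prediction_table(pred, "scored.tsv")
```

A thin command-line interface (`exec/interformer`) exposes the same
pipeline as `synth`, `build-dataset`, `train`, `predict`, `eval` and
`analyze` subcommands.

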