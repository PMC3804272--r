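# barocomp

Comparative amino-acid composition of barophilic and nonbarophilic
proteomes, stratified by protein structural context and by the
evolutionary age of fold-superfamily (FSF) domains.

## The problem

Barophiles (piezophiles) — organisms adapted to high hydrostatic pressure —
show directional amino-acid substitution relative to their low-pressure
relatives: Arg, Ser, Val, Asp and Gly tend to be gained by the barophile,
while Asn, Lys, Pro, Ile, Thr, Gln and Tyr tend to be gained by the
nonbarophile. The strength of these preferences is summarised by the
barophily rank (BR; 20 = most barophilic, 1 = least), packaged here as a
reference table. `barocomp` is for molecular-evolution researchers who want
to localise this compositional bias: does it arise in domain regions or in
the intervening sequence between domains, in shared or species-specific
folds, and in evolutionarily ancient or recent domains?

## The statistic

For a region the relative abundance of amino acid *a* is
count(*a*) / (standard residues in the region); averaging over the
sequences of a group gives the mean relative amino-acid abundance, MAA.
The analysis reports, per amino acid and per context,

Δ(a) = MAA_barophile(a) − MAA_nonbarophile(a),

tested with Welch's two-sample *t*-test (Welch–Satterthwaite df,
two-sided), annotated with stars at \*p < 0.1, \*\*p < 0.01,
\*\*\*p < 0.001, \*\*\*\*p < 0.0001. A positive Δ means barophile-tilted
usage. Contexts: whole sequences; intervening regions; shared-FSF and
specific-FSF domain regions; and matched FSFs of homologous pairs with
identical FSF assignments (repeat-averaged within sequences, difference
within pairs, averaged within FSFs), optionally restricted to ancient
(nd ∈ [0, 0.2]) or recent (nd ∈ [0.6, 1]) FSFs. Domain ages come from node
distances (nd) on a rooted FSF phylogenomic tree, mapped to geological
time by the linear molecular clock *t* = −3.831·nd + 3.628 Gy.

Because real analyses of this kind need external structural census data, a
synthetic-data module generates proteome pairs with planted, configurable
biases (tilt δ on domain-region residue frequencies, modulated per age
stratum), so every stage is verifiable by parameter recovery against
closed-form expectations.

## Worked example

```r
library(barocomp)

sim    <- simulate_proteome_pair(sim_config(seed = 1))  # delta = 0.2 defaults
report <- run_analysis(sim)
report
#> barocomp report
#>   sequences: a = 340 , b = 340
#>   FSFs: a = 108 , b = 108 , shared = 96
#>   homolog pairs by category: cat1 5, cat2 7, cat3 12, cat4 12, cat5 264
#>   matched FSFs: 96
#>   consistently preferred: R, S, V, D, G, N, K, P, I, T, Q, Y

head(report$comparisons$shared_fsf[, c("aa","class","rank","diff","t","p","stars")], 6)
#>   aa class rank    diff    t        p stars
#> 1  R     B   20  0.0212 21.1 4.59e-73  ****
#> 2  S     B   19  0.0225 21.7 4.32e-76  ****
#> 3  V     B   18  0.0208 20.8 2.62e-71  ****
#> 4  D     B   17  0.0225 22.4 5.46e-79  ****
#> 5  G     B   16  0.0229 22.4 2.91e-79  ****
#> 6  N     N    7 -0.0187 17.6 1.04e-55  ****
```

Reading this: in shared-FSF domain regions the five class-B amino acids
are used ~0.021–0.023 more (in relative-abundance units) by the simulated
barophile, the seven class-N amino acids ~0.016–0.019 less — close to the
planted closed-form expectations (+0.0220 / −0.0180) — and the preference
grid flags exactly the twelve biased amino acids as consistent. With
`delta = 0` the same pipeline produces no flags (null calibration), and
with the bias confined to ancient FSFs
(`bias_by_stratum = c(ancient = 1, neither = 0, recent = 0)`) the signal
appears in the ancient matched-FSF comparison and vanishes in the recent
one.

Real data enter through the same readers the simulator writes for:
`read_fasta()`, `read_domain_assignments()` (TSV with `"start-end[,...]"`
region strings), `read_homolog_pairs()`, and a Newick tree
(`fsf_age_table()`) or precomputed nd table (`read_fsf_age_table()`);
`read_bundle()`/`run_analysis()` orchestrate, `write_report()` emits TSV
tables plus a YAML run manifest.

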