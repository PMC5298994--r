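# poreperm

Connexin (Cx) hemichannels are plasma-membrane channels permeable to ions
and small molecules. Which fluorescent tracers pass through a given
hemichannel — and which do not — carries information about the chemistry
and geometry of its pore. `poreperm` implements the computational side of a
hemichannel permeability characterization for users in channel biophysics
and cheminformatics:

1. **Descriptor subset selection.** Given a molecules × descriptors table
   (PaDEL-style) with permeant / non-permeant labels, an elitist genetic
   algorithm (GA) searches binary subsets of descriptors, scoring each
   subset by the number of molecules a K-nearest-neighbor (KNN) classifier
   gets right under leave-one-out (LOO) cross-validation. The GA keeps a
   population of 5,000 subsets, passes the top 1,000 unchanged to the next
   generation, and fills the rest by single-point crossover of elite pairs
   plus per-bit point mutation at rate 10⁻³.
2. **Pore-radius profiling.** For a channel structure (PDB), the pore
   radius along a fixed axis is r(z) = min over atoms of
   (‖p(z) − xᵢ‖ − vdWᵢ), clamped to [0, 16 Å], sampled every 0.5 Å over a
   120 Å (hemichannel) or 200 Å (gap junction channel) axis — the radius of
   the largest axis-centered sphere that fits the lumen at each height.
3. **Assay quantification.** Junctional conductance g_j = −I_b/(V_a − V_b)
   from dual voltage clamp; half-amplitude threshold idealization of
   single-channel current traces into open/closed events; unitary
   conductance (pS) and open probability P_o; per-phase dye-uptake slopes
   (AU/min) by ordinary least squares; and the ratiometric Fura-2 calcium
   signal F340/F380.

The published 16-dye uptake panel and the 9 × 11 table of selected
descriptors (categories: electronegativity, ionization potential,
polarizability, size and geometry, topological flexibility, valence) ship
as checksummed fixtures. A `synthetic_data` module generates every input
the pipeline consumes — planted two-class descriptor matrices, two-state
Markov channel traces, phase-structured uptake time courses, and
pseudo-atom ring pore geometries with closed-form radius oracles — so the
whole pipeline is testable without downloads.

## Worked example

```r
library(poreperm)

dm <- load_descriptor_table()     # 9 molecules x 11 descriptors, labelled
res <- run_ga(dm, ga_config(population_size = 500L, elite_size = 100L,
                            offspring_size = 400L, seed = 1L,
                            max_generations = 30L, stall_generations = 5L))
res
#> <ga_result: fitness 9 after 6 generation(s); 1 descriptor(s) selected>
#> selected: VP-6

loo_fitness(standardize(dm), subset = "TDB6e", k = 1)
#> <loo_result: 9/9 correct>

head(separation_report(dm)[, c("descriptor", "separates", "direction")], 4)
#>        descriptor separates       direction
#> TDB6e       TDB6e      TRUE permeant_higher
#> ATSC5s     ATSC5s      TRUE  permeant_lower
#> GATS5s     GATS5s      TRUE permeant_higher
#> TDB8i       TDB8i      TRUE permeant_higher

tr  <- gen_channel_trace(g = 75, P_o = 0.9, V = 60, noise_sd = 0.5,
                         duration_s = 40, seed = 2)
est <- conductance_estimate(detect_events(tr), V = 60)
sprintf("modal conductance: %g pS; P_o = %.3f", est$modal_conductance,
        est$open_probability)
#> "modal conductance: 75 pS; P_o = 0.900"
```

The GA reaches the maximum fitness of 9/9 correctly classified molecules —
single descriptors such as TDB6e or VP-6 already separate the two classes
perfectly on this table, which is why the parsimony tie-break settles on a
singleton. The separation report shows each descriptor's class ranges:
`permeant_higher` means every permeant molecule's value exceeds every
non-permeant one's. The simulated 75 pS channel at open probability 0.9 is
recovered exactly by the event idealization.

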