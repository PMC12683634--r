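# Hydration free energies for H2O and OH- (kcal/mol), from alchemical
# charging simulations in bulk water and at the MAO A reactive site.
# Legs dG9..dG12 are the counterion thermodynamic cycles:
#   dG9:  OH0 + Na0 -> OH- + Na+
#   dG10: OH0 + Na+ -> OH- + Na0
#   dG11: OH0 -> OH-
#   dG12: Na0 -> Na+
environment	leg	value	uncertainty
water	dG_H2O	-6.87	0.01
water	dG9	-205.93	0.05
water	dG10	-34.51	0.08
water	dG11	-120.16	0.04
water	dG12	-85.68	0.04
protein	dG_H2O	-9.76	0.44
protein	dG9	-197.74	1.97
protein	dG10	-27.26	2.21
protein	dG11	-113.82	0.51
protein	dG12	-86.52	0.09
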