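id	name	ob	dl	herbs
S01	"methyl palmitate"	NA	NA	"Moschus"
S02	"triolein"	NA	NA	"Moschus"
S03	"methyl-9-octadecenoate"	NA	NA	"Moschus"
S04	"normuscone"	NA	NA	"Moschus"
S05	"cholest-4-ene-3-one"	NA	NA	"Moschus"
S06	"Delta4-cholestenone-3"	NA	NA	"Moschus"
S07	"cholestanol"	NA	NA	"Moschus"
S08	"cholic acid"	NA	NA	"Moschus"
S09	"3alpha-hydroxyandrostan-4-en-17beta-one"	NA	NA	"Moschus"
S10	"3alpha-hydroxy-5alpha-androstan-17-one"	NA	NA	"Moschus"
S11	"hydroxymuscopyridine A"	NA	NA	"Moschus"
S12	"androstan-4,6-dien-3,17-dione"	NA	NA	"Moschus"
S13	"androst-4-en-3,17-dione"	NA	NA	"Moschus"
S14	"5beta-androstane-3,17-dione"	NA	NA	"Moschus"
S15	"5beta-androstane-3alpha,17beta-diol"	NA	NA	"Moschus"
S16	"5alpha-androstane-3beta,17alpha-diol"	NA	NA	"Moschus"
S17	"musclide A1"	NA	NA	"Moschus"
S18	"muscopyridine"	NA	NA	"Moschus"
S19	"muscone"	NA	NA	"Moschus"
S20	"hydroxymuscopyridine B"	NA	NA	"Moschus"
S21	"3beta-hydroxy-androst-5-en-17-one"	NA	NA	"Moschus"
L01	"dihydroionone"	NA	NA	"Ambra Grisea"
L02	"alpha-ambrinol"	NA	NA	"Ambra Grisea"
L03	"ambrein"	NA	NA	"Ambra Grisea"
L04	"(-)-a-Ambreinolide"	NA	NA	"Ambra Grisea"
L05	"(+)-amber aldehyde"	NA	NA	"Ambra Grisea"
L06	"(-)-Ambrox"	NA	NA	"Ambra Grisea"
L07	"gamma-homocyclogeranyl chloride"	NA	NA	"Ambra Grisea"
L08	"epicoprosterol"	NA	NA	"Ambra Grisea"
L09	"ambrein"	NA	NA	"Ambra Grisea"
N01	"dihydrotestosterone"	NA	NA	"Bullwhip"
N02	"undecanoic acid"	NA	NA	"Bullwhip"
N03	"heptadecenoic acid"	NA	NA	"Bullwhip"
N04	"caproic acid"	NA	NA	"Bullwhip"
N05	"estradiol"	NA	NA	"Bullwhip"
N06	"testosterone"	NA	NA	"Bullwhip"
N07	"cholesterol"	NA	NA	"Bullwhip, Myristicae Semena, Moschus"
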