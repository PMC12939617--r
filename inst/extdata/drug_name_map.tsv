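verbatim	generic	is_combination	drug_class
DIFLUPREDNATE	DIFLUPREDNATE	0	glucocorticoid
DUREZOL	DIFLUPREDNATE	0	glucocorticoid
DIFLUPREDNATE OPHTHALMIC EMULSION	DIFLUPREDNATE	0	glucocorticoid
PREDNISOLONE ACETATE	PREDNISOLONE ACETATE	0	glucocorticoid
PRED FORTE	PREDNISOLONE ACETATE	0	glucocorticoid
OMNIPRED	PREDNISOLONE ACETATE	0	glucocorticoid
PREDNISOLONE	PREDNISOLONE	0	glucocorticoid
PREDNISOLONE SODIUM PHOSPHATE	PREDNISOLONE	0	glucocorticoid
ORAPRED	PREDNISOLONE	0	glucocorticoid
PRELONE	PREDNISOLONE	0	glucocorticoid
PREDNISONE	PREDNISONE	0	glucocorticoid
DELTASONE	PREDNISONE	0	glucocorticoid
RAYOS	PREDNISONE	0	glucocorticoid
TRIAMCINOLONE ACETONIDE	TRIAMCINOLONE ACETONIDE	0	glucocorticoid
KENALOG	TRIAMCINOLONE ACETONIDE	0	glucocorticoid
TRIESENCE	TRIAMCINOLONE ACETONIDE	0	glucocorticoid
FLUTICASONE FUROATE	FLUTICASONE FUROATE	0	glucocorticoid
ARNUITY ELLIPTA	FLUTICASONE FUROATE	0	glucocorticoid
FLUTICASONE PROPIONATE	FLUTICASONE PROPIONATE	0	glucocorticoid
FLOVENT	FLUTICASONE PROPIONATE	0	glucocorticoid
FLONASE	FLUTICASONE PROPIONATE	0	glucocorticoid
DEXAMETHASONE	DEXAMETHASONE	0	glucocorticoid
DEXAMETHASONE SODIUM PHOSPHATE	DEXAMETHASONE	0	glucocorticoid
DECADRON	DEXAMETHASONE	0	glucocorticoid
BUDESONIDE	BUDESONIDE	0	glucocorticoid
PULMICORT	BUDESONIDE	0	glucocorticoid
ENTOCORT	BUDESONIDE	0	glucocorticoid
METHYLPREDNISOLONE	METHYLPREDNISOLONE	0	glucocorticoid
METHYLPREDNISOLONE SODIUM SUCCINATE	METHYLPREDNISOLONE	0	glucocorticoid
SOLU-MEDROL	METHYLPREDNISOLONE	0	glucocorticoid
MEDROL	METHYLPREDNISOLONE	0	glucocorticoid
HYDROCORTISONE	HYDROCORTISONE	0	glucocorticoid
HYDROCORTISONE SODIUM SUCCINATE	HYDROCORTISONE	0	glucocorticoid
CORTEF	HYDROCORTISONE	0	glucocorticoid
IVACAFTOR	IVACAFTOR	0	cftr_modulator
KALYDECO	IVACAFTOR	0	cftr_modulator
ELEXACAFTOR/IVACAFTOR/TEZACAFTOR	ELEXACAFTOR/IVACAFTOR/TEZACAFTOR	1	cftr_modulator
ELEXACAFTOR/TEZACAFTOR/IVACAFTOR	ELEXACAFTOR/IVACAFTOR/TEZACAFTOR	1	cftr_modulator
TRIKAFTA	ELEXACAFTOR/IVACAFTOR/TEZACAFTOR	1	cftr_modulator
IVACAFTOR/LUMACAFTOR	IVACAFTOR/LUMACAFTOR	1	cftr_modulator
LUMACAFTOR/IVACAFTOR	IVACAFTOR/LUMACAFTOR	1	cftr_modulator
ORKAMBI	IVACAFTOR/LUMACAFTOR	1	cftr_modulator
ADALIMUMAB	ADALIMUMAB	0	monoclonal_antibody
HUMIRA	ADALIMUMAB	0	monoclonal_antibody
ADALIMUMAB-ATTO	ADALIMUMAB	0	monoclonal_antibody
INFLIXIMAB	INFLIXIMAB	0	monoclonal_antibody
REMICADE	INFLIXIMAB	0	monoclonal_antibody
RANIBIZUMAB	RANIBIZUMAB	0	monoclonal_antibody
LUCENTIS	RANIBIZUMAB	0	monoclonal_antibody
METHOTREXATE	METHOTREXATE	0	immunosuppressant
METHOTREXATE SODIUM	METHOTREXATE	0	immunosuppressant
TREXALL	METHOTREXATE	0	immunosuppressant
MYCOPHENOLATE MOFETIL	MYCOPHENOLATE MOFETIL	0	immunosuppressant
MYCOPHENOLATE MOFETIL HYDROCHLORIDE	MYCOPHENOLATE MOFETIL	0	immunosuppressant
CELLCEPT	MYCOPHENOLATE MOFETIL	0	immunosuppressant
MELPHALAN	MELPHALAN	0	antineoplastic
MELPHALAN HYDROCHLORIDE	MELPHALAN	0	antineoplastic
ALKERAN	MELPHALAN	0	antineoplastic
TOPOTECAN	TOPOTECAN	0	antineoplastic
TOPOTECAN HYDROCHLORIDE	TOPOTECAN	0	antineoplastic
HYCAMTIN	TOPOTECAN	0	antineoplastic
CISPLATIN	CISPLATIN	0	antineoplastic
PLATINOL	CISPLATIN	0	antineoplastic
TOPIRAMATE	TOPIRAMATE	0	antiepileptic
TOPAMAX	TOPIRAMATE	0	antiepileptic
FILGRASTIM	FILGRASTIM	0	colony_stimulating_factor
NEUPOGEN	FILGRASTIM	0	colony_stimulating_factor
FILGRASTIM-SNDZ	FILGRASTIM	0	colony_stimulating_factor
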