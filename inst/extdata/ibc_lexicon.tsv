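surface_form	canonical_id	entity_type
IBC	IBC	disease
inflammatory breast cancer	IBC	disease
Retinoblastoma	H01513	disease
Neuroblastoma	H00043	disease
Medulloblastoma	H01667	disease
Glioma	H00042	disease
Meningioma	H01556	disease
Osteosarcoma	H00036	disease
Ewing sarcoma	H00035	disease
Rhabdomyosarcoma	H00037	disease
Synovial sarcoma	H00050	disease
Angiosarcoma	H01666	disease
B-cell acute lymphocytic leukemia	H00001	disease
T-cell acute lymphocytic leukemia	H00002	disease
Nasopharyngeal cancer	H00054	disease
Salivary gland cancer	H01508	disease
Tonsillar cancer	H01509	disease
Cancer of the anal canal	H00044	disease
Fallopian tube cancer	H01554	disease
Primary peritoneal carcinoma	H01665	disease
breast cancer	H00031	disease
Carboplatin	DB00958	drug
Carmustine	DB00262	drug
Cytarabine	DB00987	drug
Dacarbazine	DB00851	drug
Daunorubicin	DB00694	drug
Docetaxel	DB01248	drug
Doxorubicin	DB00997	drug
Etoposide	DB00773	drug
Fluorouracil	DB00544	drug
Gefitinib	DB00317	drug
Gemcitabine	DB00441	drug
Hydroxyurea	DB01005	drug
Ifosfamide	DB01181	drug
Imatinib	DB00619	drug
Lapatinib	DB01259	drug
Methotrexate	DB00563	drug
Mitoxantrone	DB01204	drug
Octreotide	DB00104	drug
Paclitaxel	DB01229	drug
Prednisone	DB00635	drug
Sunitinib	DB01268	drug
Topotecan	DB01030	drug
Vincristine	DB00541	drug
Vinorelbine	DB00361	drug
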