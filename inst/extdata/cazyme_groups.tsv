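family	group
GH5-1	cellulase
GH5-2	cellulase
GH5-22	cellulase
GH5-25	cellulase
GH5-26	cellulase
GH5-37	cellulase
GH5-38	cellulase
GH5-4	cellulase
GH5-46	cellulase
GH5-5	cellulase
GH5-52	cellulase
GH5-53	cellulase
GH5-55	cellulase
GH6	cellulase
GH7	cellulase
GH8	cellulase
GH9	cellulase
GH12	cellulase
GH44	cellulase
GH45	cellulase
GH48	cellulase
GH74	cellulase
GH124	cellulase
GH131	cellulase
AA9	cellulase
AA10	cellulase
AA3-1	cellulase
AA15	cellulase
AA16	cellulase
GH5-21	xylanase
GH5-34	xylanase
GH5-35	xylanase
GH10	xylanase
GH11	xylanase
GH30-7	xylanase
GH30-8	xylanase
AA14	xylanase
GH43-17	xylanase
GH43-7	xylanase
AA1-1	ligninolytic
AA1-2	ligninolytic
AA1-3	ligninolytic
AA2	ligninolytic
GH1	oh_pbh
GH2	oh_pbh
GH3	oh_pbh
GH116	oh_pbh
GH39	oh_pbh
GH40	oh_pbh
GH43-1	oh_pbh
GH43-10	oh_pbh
GH43-11	oh_pbh
GH43-12	oh_pbh
GH43-14	oh_pbh
GH43-16	oh_pbh
GH43-18	oh_pbh
GH43-19	oh_pbh
GH43-2	oh_pbh
GH43-20	oh_pbh
GH43-21	oh_pbh
GH43-22	oh_pbh
GH43-23	oh_pbh
GH43-26	oh_pbh
GH43-27	oh_pbh
GH43-29	oh_pbh
GH43-30	oh_pbh
GH43-32	oh_pbh
GH43-33	oh_pbh
GH43-34	oh_pbh
GH43-35	oh_pbh
GH43-36	oh_pbh
GH43-37	oh_pbh
GH43-4	oh_pbh
GH43-5	oh_pbh
GH43-9	oh_pbh
GH5-43	oh_pbh
GH5-45	oh_pbh
CE1	oh_pbh
CE2	oh_pbh
CE3	oh_pbh
CE4	oh_pbh
CE5	oh_pbh
CE6	oh_pbh
CE7	oh_pbh
CE12	oh_pbh
CE16	oh_pbh
GH5-9	oh_pbh
GH95	oh_pbh
GH62	oh_pbh
GH67	oh_pbh
GH52	oh_pbh
GH54	oh_pbh
GH120	oh_pbh
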