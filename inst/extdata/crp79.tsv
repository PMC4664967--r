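name	subunit
RPSA	40S
RPS2	40S
RPS3	40S
RPS3A	40S
RPS4	40S
RPS5	40S
RPS6	40S
RPS7	40S
RPS8	40S
RPS9	40S
RPS10	40S
RPS11	40S
RPS12	40S
RPS13	40S
RPS14	40S
RPS15	40S
RPS15A	40S
RPS16	40S
RPS17	40S
RPS18	40S
RPS19	40S
RPS20	40S
RPS21	40S
RPS23	40S
RPS24	40S
RPS25	40S
RPS26	40S
RPS27	40S
RPS27A	40S
RPS28	40S
RPS29	40S
RPS30	40S
RPLP0	60S
RPLP1	60S
RPLP2	60S
RPL3	60S
RPL4	60S
RPL5	60S
RPL6	60S
RPL7	60S
RPL7A	60S
RPL8	60S
RPL9	60S
RPL10	60S
RPL10A	60S
RPL11	60S
RPL12	60S
RPL13	60S
RPL13A	60S
RPL14	60S
RPL15	60S
RPL17	60S
RPL18	60S
RPL18A	60S
RPL19	60S
RPL21	60S
RPL22	60S
RPL23	60S
RPL23A	60S
RPL24	60S
RPL26	60S
RPL27	60S
RPL27A	60S
RPL28	60S
RPL29	60S
RPL30	60S
RPL31	60S
RPL32	60S
RPL34	60S
RPL35	60S
RPL35A	60S
RPL36	60S
RPL36A	60S
RPL37	60S
RPL37A	60S
RPL38	60S
RPL39	60S
RPL40	60S
RPL41	60S
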